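#' Expression matrix container
#'
#' Holds a genes x samples numeric matrix together with row/column identifiers,
#' optional observation-level weights, optional sample weights, and a `kind`
#' declaring the measurement scale. `kind = "counts"` requires non-negative,
#' non-missing values; missing values are allowed only for
#' `kind = "log_intensity"`.
#'
#' @param values Numeric matrix, genes in rows, samples in columns.
#' @param gene_ids Character vector of row identifiers (default: rownames).
#' @param sample_ids Character vector of column identifiers (default: colnames).
#' @param kind One of `"log_intensity"`, `"counts"`, `"logcpm"`.
#' @param obs_weights Optional positive finite matrix, same shape as `values`.
#' @param sample_weights Optional positive vector, one entry per sample.
#' @return An object of class `"ExpressionMatrix"`.
#' @export
expression_matrix <- function(values,
                              gene_ids = rownames(values),
                              sample_ids = colnames(values),
                              kind = c("log_intensity", "counts", "logcpm"),
                              obs_weights = NULL,
                              sample_weights = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(ncol(values)))
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (length(gene_ids) != nrow(values))
    stop("length(gene_ids) must equal nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("length(sample_ids) must equal ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids are not allowed")
  if (kind != "log_intensity" && anyNA(values))
    stop("missing values are only permitted for kind = 'log_intensity'")
  if (kind == "counts" && any(values < 0, na.rm = TRUE))
    stop("kind = 'counts' requires non-negative values")
  if (!is.null(obs_weights)) {
    obs_weights <- as.matrix(obs_weights)
    if (!all(dim(obs_weights) == dim(values)))
      stop("obs_weights must have the same dimensions as values")
    if (!all(is.finite(obs_weights)) || any(obs_weights <= 0))
      stop("obs_weights must be positive and finite")
  }
  if (!is.null(sample_weights)) {
    sample_weights <- as.numeric(sample_weights)
    if (length(sample_weights) != ncol(values))
      stop("sample_weights must have one entry per sample")
    if (!all(is.finite(sample_weights)) || any(sample_weights <= 0))
      stop("sample_weights must be positive and finite")
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(values = values, gene_ids = gene_ids,
                 sample_ids = sample_ids, kind = kind,
                 obs_weights = obs_weights, sample_weights = sample_weights),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix (%s): %d genes x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  if (!is.null(x$obs_weights)) cat("  with observation weights\n")
  if (!is.null(x$sample_weights)) cat("  with sample weights\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
as.matrix.ExpressionMatrix <- function(x, ...) x$values

#' Subset an ExpressionMatrix by genes and/or samples
#' @param x ExpressionMatrix.
#' @param i,j Gene / sample indices (any form accepted by matrix subsetting).
#' @param ... Unused.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expression_matrix(x$values[i, j, drop = FALSE],
                    kind = x$kind,
                    obs_weights = if (!is.null(x$obs_weights))
                      x$obs_weights[i, j, drop = FALSE],
                    sample_weights = if (!is.null(x$sample_weights)) {
                      sw <- x$sample_weights
                      names(sw) <- x$sample_ids
                      unname(sw[j])
                    })
}

#' Design specification
#'
#' A samples x coefficients design matrix with coefficient names and an
#' optional contrast matrix mapping coefficients to tested contrasts.
#'
#' @param design Numeric matrix, one row per sample.
#' @param coef_names Coefficient names (default: column names).
#' @param contrasts Optional numeric matrix with `ncol(design)` rows.
#' @return An object of class `"DesignSpec"`.
#' @export
design_spec <- function(design, coef_names = colnames(design),
                        contrasts = NULL) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  if (is.null(coef_names)) coef_names <- paste0("coef", seq_len(ncol(design)))
  if (length(coef_names) != ncol(design))
    stop("coef_names must name every design column")
  colnames(design) <- coef_names
  if (!is.null(contrasts)) {
    contrasts <- as.matrix(contrasts)
    if (nrow(contrasts) != ncol(design))
      stop("contrast rows must align with design coefficients")
    if (is.null(colnames(contrasts)))
      colnames(contrasts) <- paste0("c", seq_len(ncol(contrasts)))
    rownames(contrasts) <- coef_names
  }
  structure(list(design = design, coef_names = coef_names,
                 contrasts = contrasts), class = "DesignSpec")
}

#' @export
print.DesignSpec <- function(x, ...) {
  cat(sprintf("DesignSpec: %d samples x %d coefficients (%s)\n",
              nrow(x$design), ncol(x$design),
              paste(x$coef_names, collapse = ", ")))
  if (!is.null(x$contrasts))
    cat(sprintf("  contrasts: %s\n", paste(colnames(x$contrasts),
                                           collapse = ", ")))
  invisible(x)
}

# Coerce a design argument (matrix or DesignSpec) to a checked DesignSpec.
as_design_spec <- function(design, require_full_rank = TRUE) {
  if (!inherits(design, "DesignSpec")) design <- design_spec(design)
  if (require_full_rank) {
    qr_d <- qr(design$design)
    if (qr_d$rank < ncol(design$design)) {
      dep <- design$coef_names[qr_d$pivot[-seq_len(qr_d$rank)]]
      stop("design matrix is not of full column rank; dependent columns: ",
           paste(dep, collapse = ", "))
    }
  }
  design
}

#' Gene set collection
#'
#' Named gene-identifier sets with optional per-gene direction (+1/-1) and
#' weight annotations. Gene ids are opaque strings matched exactly.
#'
#' @param sets Named list of character vectors (each non-empty).
#' @param directions Optional named list (per set) of +1/-1 vectors named by
#'   gene id; keys must be members of the corresponding set.
#' @param gene_weights Optional named list (per set) of numeric vectors named
#'   by gene id.
#' @param descriptions Optional character vector of set descriptions.
#' @return An object of class `"GeneSetCollection"`.
#' @export
gene_set_collection <- function(sets, directions = NULL, gene_weights = NULL,
                                descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("every gene set must be named")
  lens <- lengths(sets)
  if (any(lens == 0)) stop("empty gene sets are not allowed: ",
                           paste(names(sets)[lens == 0], collapse = ", "))
  sets <- lapply(sets, as.character)
  check_annot <- function(ann, what) {
    if (is.null(ann)) return(NULL)
    for (nm in names(ann)) {
      if (!nm %in% names(sets)) stop(what, " refers to unknown set ", nm)
      extra <- setdiff(names(ann[[nm]]), sets[[nm]])
      if (length(extra)) stop(what, " for set ", nm,
                              " names genes outside the set")
    }
    ann
  }
  directions <- check_annot(directions, "directions")
  if (!is.null(directions) &&
      !all(unlist(directions, use.names = FALSE) %in% c(-1, 1)))
    stop("directions must be +1 or -1")
  gene_weights <- check_annot(gene_weights, "gene_weights")
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(sets)),
                                                      names(sets))
  structure(list(sets = sets, directions = directions,
                 gene_weights = gene_weights, descriptions = descriptions),
            class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets (sizes %d-%d)\n", length(x$sets),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.GeneSetCollection <- function(x) length(x$sets)

#' Classification of genes x contrasts into down/not-significant/up
#'
#' @param codes Integer matrix with entries in -1, 0, +1.
#' @param method,adjust_method,p_threshold,lfc_threshold Metadata recording how
#'   the classification was made.
#' @return An object of class `"TestResults"`.
#' @export
test_results <- function(codes, method = "separate", adjust_method = "BH",
                         p_threshold = 0.05, lfc_threshold = 0) {
  codes <- as.matrix(codes)
  if (!all(codes %in% c(-1L, 0L, 1L)))
    stop("TestResults codes must be -1, 0 or +1")
  storage.mode(codes) <- "integer"
  structure(list(codes = codes, method = method,
                 adjust_method = adjust_method, p_threshold = p_threshold,
                 lfc_threshold = lfc_threshold), class = "TestResults")
}

#' @export
print.TestResults <- function(x, ...) {
  cat(sprintf("TestResults (%s, %s at p<=%g, lfc>=%g)\n", x$method,
              x$adjust_method, x$p_threshold, x$lfc_threshold))
  tab <- apply(x$codes, 2, function(cc) c(down = sum(cc == -1),
                                          ns = sum(cc == 0),
                                          up = sum(cc == 1)))
  print(tab)
  invisible(x)
}

#' @export
summary.TestResults <- function(object, ...) {
  apply(object$codes, 2, function(cc) c(down = sum(cc == -1),
                                        ns = sum(cc == 0),
                                        up = sum(cc == 1)))
}

#' @export
print.LinearFit <- function(x, ...) {
  cat(sprintf("LinearFit: %d genes, coefficients: %s\n",
              nrow(x$coefficients),
              paste(colnames(x$coefficients), collapse = ", ")))
  if (!is.null(x$t)) cat(sprintf("  moderated (df_prior = %s)\n",
                                 format(x$df_prior[1], digits = 4)))
  invisible(x)
}

# Run code with a fixed, fully pinned RNG state and restore afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(code)
}
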