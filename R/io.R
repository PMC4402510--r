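#' Read an expression matrix from TSV/CSV or MatrixMarket files
#'
#' Delimited files must carry a header row of sample ids and gene ids in the
#' first column. `.csv` files are comma separated, anything else is read as
#' tab separated. A path ending in `.mtx` is read as a MatrixMarket triplet
#' file (counts only) with row and column identifiers in sibling files
#' `<path>.rows` and `<path>.cols` (one id per line).
#'
#' @param path Input file.
#' @param kind Declared scale of the values (see [expression_matrix()]).
#' @param allow_dup If `TRUE`, duplicated gene ids are made unique by
#'   suffixing; otherwise they are an error.
#' @return An [expression_matrix()].
#' @export
read_matrix <- function(path, kind = c("log_intensity", "counts", "logcpm"),
                        allow_dup = FALSE) {
  kind <- match.arg(kind)
  if (grepl("\\.mtx$", path)) {
    if (kind != "counts")
      stop("MatrixMarket input is only supported for kind = 'counts'")
    m <- as.matrix(Matrix::readMM(path))
    rows <- readLines(paste0(path, ".rows"))
    cols <- readLines(paste0(path, ".cols"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m))
      stop("row/col name files do not match the MatrixMarket dimensions")
    ids <- fix_dup_ids(rows, allow_dup)
    return(expression_matrix(m, gene_ids = ids, sample_ids = cols,
                             kind = kind))
  }
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           comment.char = "#", quote = "\"")
  if (ncol(raw) < 2) stop("expected gene-id column plus >=1 sample column")
  ids <- fix_dup_ids(raw[[1]], allow_dup)
  samples <- colnames(raw)[-1]
  vals <- matrix(NA_real_, nrow(raw), length(samples))
  for (j in seq_along(samples)) {
    cellv <- raw[[j + 1]]
    na_cell <- is.na(cellv) | cellv %in% c("NA", "")
    num <- suppressWarnings(as.numeric(cellv))
    bad <- which(is.na(num) & !na_cell)
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at row '%s', column '%s'",
                   cellv[bad[1]], ids[bad[1]], samples[j]))
    if (kind != "log_intensity" && any(na_cell))
      stop(sprintf("missing value at row '%s', column '%s' not permitted for kind = '%s'",
                   ids[which(na_cell)[1]], samples[j], kind))
    vals[, j] <- num
  }
  expression_matrix(vals, gene_ids = ids, sample_ids = samples, kind = kind)
}

fix_dup_ids <- function(ids, allow_dup) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) {
    if (!allow_dup)
      stop("duplicate gene ids found (first: ",
           ids[which(duplicated(ids))[1]],
           "); pass allow_dup = TRUE to suffix them")
    ids <- make.unique(ids, sep = ".")
  }
  ids
}

#' Write an expression matrix as TSV
#'
#' Values are written with full double precision (`%.17g`) so that a
#' read/write cycle reproduces finite values exactly.
#'
#' @param m ExpressionMatrix.
#' @param path Output file.
#' @param id_col Name for the gene-id column.
#' @export
write_matrix <- function(m, path, id_col = "id") {
  body <- apply(m$values, 2, function(col)
    ifelse(is.na(col), "NA", sprintf("%.17g", col)))
  body <- matrix(body, nrow = nrow(m$values))
  lines <- c(paste(c(id_col, m$sample_ids), collapse = "\t"),
             vapply(seq_len(nrow(body)), function(i)
               paste(c(m$gene_ids[i], body[i, ]), collapse = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a design matrix or build one from a targets file
#'
#' In explicit mode the file is a numeric samples x coefficients TSV with a
#' header of coefficient names and sample ids in the first column; the matrix
#' must be of full column rank. In targets mode the file has two columns
#' (sample, group) and a treatment-means design is built: one indicator
#' column per group level, levels ordered by first appearance, so every row
#' sums to 1.
#'
#' @param path Input file (TSV; `.csv` accepted for explicit matrices).
#' @param targets_mode Interpret the file as a targets file.
#' @return A [design_spec()].
#' @export
read_design <- function(path, targets_mode = FALSE) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  if (targets_mode) {
    if (ncol(tab) < 2) stop("targets file needs columns: sample, group")
    groups <- as.character(tab[[2]])
    levels_seen <- unique(groups)
    design <- vapply(levels_seen, function(g) as.numeric(groups == g),
                     numeric(length(groups)))
    design <- matrix(design, nrow = length(groups),
                     dimnames = list(as.character(tab[[1]]), levels_seen))
    return(design_spec(design, coef_names = levels_seen))
  }
  ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  as_design_spec(design_spec(mat))
}

#' Read a GMT gene set file
#'
#' Standard GMT lines are `name TAB description TAB member...`. Member tokens
#' may carry direction and weight extensions: `gene,+1` or `gene,+1,0.8`.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); dirs <- list(); wts <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("GMT line %d has fewer than 3 fields", i))
    name <- fields[1]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT line %d (%s) has an empty member list", i, name))
    toks <- strsplit(members, ",", fixed = TRUE)
    genes <- vapply(toks, `[[`, "", 1)
    sets[[name]] <- genes
    desc[name] <- fields[2]
    has_dir <- lengths(toks) >= 2
    if (any(has_dir)) {
      d <- as.numeric(vapply(toks[has_dir], `[[`, "", 2))
      if (any(is.na(d)) || !all(d %in% c(-1, 1)))
        stop(sprintf("GMT line %d: direction tokens must be +1 or -1", i))
      dirs[[name]] <- setNames(d, genes[has_dir])
    }
    has_w <- lengths(toks) >= 3
    if (any(has_w)) {
      w <- as.numeric(vapply(toks[has_w], `[[`, "", 3))
      if (any(is.na(w)))
        stop(sprintf("GMT line %d: weight tokens must be numeric", i))
      wts[[name]] <- setNames(w, genes[has_w])
    }
  }
  gene_set_collection(sets,
                      directions = if (length(dirs)) dirs,
                      gene_weights = if (length(wts)) wts,
                      descriptions = desc)
}

#' Write a gene set collection as GMT
#' @param sets GeneSetCollection.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets$sets), function(nm) {
    genes <- sets$sets[[nm]]
    toks <- genes
    d <- sets$directions[[nm]]
    w <- sets$gene_weights[[nm]]
    if (!is.null(d)) {
      dd <- d[genes]
      toks <- ifelse(is.na(dd), toks,
                     paste0(toks, ",", ifelse(dd > 0, "+1", "-1")))
      if (!is.null(w)) {
        ww <- w[genes]
        toks <- ifelse(is.na(ww) | is.na(dd), toks, paste0(toks, ",", ww))
      }
    }
    paste(c(nm, sets$descriptions[nm], toks), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Columns keep their given order; numeric columns are rendered at 6
#' significant digits; non-finite statistics become "NA". Optional header
#' comment lines (prefixed `# `) record provenance such as the RNG seed.
#'
#' @param rows A data.frame.
#' @param path Output file.
#' @param comments Optional character vector of comment lines.
#' @export
write_table <- function(rows, path, comments = NULL) {
  rows <- as.data.frame(rows)
  fmt <- lapply(rows, function(col) {
    if (is.double(col)) ifelse(is.finite(col), formatC(col, digits = 6,
                                                       format = "g"), "NA")
    else ifelse(is.na(col), "NA", as.character(col))
  })
  header <- paste(colnames(rows), collapse = "\t")
  body <- if (nrow(rows))
    do.call(paste, c(fmt, sep = "\t")) else character(0)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) writeLines(paste0("# ", comments), con)
  writeLines(c(header, body), con)
  invisible(path)
}

#' Serialize a LinearFit as a directory of TSV files
#' @param fit LinearFit.
#' @param dir Output directory (created if needed).
#' @export
write_fit <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(mat, name) {
    em <- expression_matrix(mat, gene_ids = rownames(mat),
                            sample_ids = colnames(mat), kind = "log_intensity")
    write_matrix(em, file.path(dir, name))
  }
  wm(fit$coefficients, "coefficients.tsv")
  wm(fit$stdev_unscaled, "stdev_unscaled.tsv")
  gene_stats <- cbind(sigma = fit$sigma, df_residual = fit$df_residual,
                      amean = fit$amean)
  rownames(gene_stats) <- rownames(fit$coefficients)
  wm(gene_stats, "gene_stats.tsv")
  wm(fit$coef_cov, "coef_cov.tsv")
  invisible(dir)
}

#' Read a LinearFit written by [write_fit()]
#' @param dir Directory.
#' @return A LinearFit (without empirical Bayes fields).
#' @export
read_fit <- function(dir) {
  rd <- function(name) {
    m <- read_matrix(file.path(dir, name), kind = "log_intensity")
    m$values
  }
  coefs <- rd("coefficients.tsv")
  gs <- rd("gene_stats.tsv")
  structure(list(coefficients = coefs,
                 stdev_unscaled = rd("stdev_unscaled.tsv"),
                 sigma = gs[, "sigma"], df_residual = gs[, "df_residual"],
                 amean = gs[, "amean"], coef_cov = rd("coef_cov.tsv"),
                 gene_ids = rownames(coefs),
                 coef_names = colnames(coefs)), class = "LinearFit")
}
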