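# Shared fixtures: small deterministic designs and contrasts.

two_group_design <- function(n_per = 3) {
  design_spec(cbind(A = rep(c(1, 0), each = n_per),
                    B = rep(c(0, 1), each = n_per)))
}

bva_contrast <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "BvA"))

# Moderated fit of a two-group simulation, for reuse across tests.
moderated_two_group <- function(sim, design) {
  moderated_stats(contrasts_fit(lm_fit(sim$m, design), bva_contrast))
}

# Smooth out the discreteness of a plus-one rotation p-value: p = k/(R+1)
# minus an independent U(0, 1/(R+1)) is exactly U(0,1) under the null.
smooth_rotation_p <- function(p, nrot, seed = 1) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  p - stats::runif(length(p)) / (nrot + 1)
}
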