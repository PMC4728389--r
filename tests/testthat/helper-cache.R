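# shared fixtures, built lazily once per session: the spectral operators and
# the full-resolution validation run are the expensive pieces
.test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .test_cache)) {
    assign(name, expr, envir = .test_cache)
  }
  get(name, envir = .test_cache)
}

ref <- gel_params()

# lighter quadrature rule: same spectral reach, ~0.1% forward accuracy,
# used where that is ample (fits, imaging)
quick_quad <- function() {
  quadrature_config(n_panels = 200, panel_rule_order = 8, tau_steps = 96)
}

ref_op <- function() {
  cached("ref_op",
         hankel_operator(ref$source, ref$initial, quadrature_config()))
}

quick_op <- function() {
  cached("quick_op", hankel_operator(ref$source, ref$initial, quick_quad()))
}

# one full-resolution validation run (oracle equivalence, mass balance,
# inversion identity, diffusive-wave signature) shared by several tests
shared_validation <- function() {
  cached("validation", {
    out <- file.path(tempdir(), "validation-shared")
    run_validate(NULL, out_dir = out)
  })
}
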