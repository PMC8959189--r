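# Shared fixtures, computed lazily and cached for the whole run.
.fx <- new.env(parent = emptyenv())

fx_mice <- function() {
  if (is.null(.fx$mice)) .fx$mice <- pymt_mice()
  .fx$mice
}

fx_scales <- function() {
  if (is.null(.fx$scales)) .fx$scales <- tme_scales(fx_mice())
  .fx$scales
}

fx_nd <- function() {
  if (is.null(.fx$nd)) .fx$nd <- tme_nondimensionalize(fx_mice(), fx_scales())
  .fx$nd
}

fx_inits <- function() {
  if (is.null(.fx$inits)) .fx$inits <- tme_inits(fx_nd())
  .fx$inits
}

fx_table3 <- function() {
  if (is.null(.fx$p3)) .fx$p3 <- tme_params_table3()
  .fx$p3
}

fx_scale_of <- function(v) {
  sc <- fx_scales()
  sc$scale[sc$variable == v]
}

# random nonnegative parameter set, reproducible
random_params <- function(seed) {
  set.seed(seed)
  tme_params(stats::setNames(stats::runif(57, 0, 0.1), tme_param_names))
}

random_state <- function(seed, max = 1) {
  set.seed(seed)
  stats::setNames(stats::runif(15, 0, max), tme_state_vars)
}
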