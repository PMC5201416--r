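# Shared fixtures: small domains and cheap solver settings so unit tests
# stay fast; scientific-scale runs live in test-acceptance.R.

tiny_params <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 40, domain_radius = 70, dx = 4, dt = 1), list(...))
  do.call(model_params, args)
}

small_sweep_params <- function(...) {
  args <- utils::modifyList(
    list(n_cells = 200, domain_radius = 126, dx = 4), list(...))
  do.call(model_params, args)
}

# Single hand-built cell layout (centers known exactly)
manual_tissue <- function(params, x, y, population = rep("Th", length(x)),
                          il2r_scale = rep(1, length(x))) {
  t0 <- data.frame(x = x, y = y, radius = params$cell_radius,
                   population = population, il2r_scale = il2r_scale)
  structure(t0, class = c("tissue", "data.frame"), params = params)
}

pstat5_anchor_obs <- function() {
  data.frame(A = 1, population = c("Th", "Treg"), fraction = c(0.11, 0.50))
}
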