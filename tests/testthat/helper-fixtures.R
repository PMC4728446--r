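# shared fixtures: reference HeLa inputs and solved states, built in code

ref_geometry <- function() {
  spindle_geometry(theta0_deg = 64, thetak_deg = 13.7, L_um = 11.1,
                   hk_um = 5.0, xk_um = 5.05, dk_um = 1.05, dbk_um = 0.24)
}

ref_architecture <- function(n_b = 14) {
  fibre_architecture(n_k = 17, n_b = n_b, kappa0_pN_um2 = 30)
}

# internal signed moment coefficients equivalent to reported loads
raw_loads <- function(F0 = 33, Fk = 280, M0 = 0) {
  spindle_loads(-F0, Fk, -M0)
}

# a self-consistent ground truth on the symmetry manifold: F0 from the
# midplane-symmetry root at the given (Fk, xj)
symmetric_truth <- function(Fk, xj, geometry = ref_geometry(),
                            architecture = ref_architecture(),
                            n_steps = 50) {
  F0 <- bridgefibre:::.F0_symmetry_root(Fk, xj, 0, geometry, architecture,
                                        n_steps)
  stopifnot(is.finite(F0))
  shape <- forward_spindle_shape(geometry, architecture,
                                 spindle_loads(F0, Fk), xj, n_steps)
  list(F0 = F0, Fk = Fk, xj = xj, shape = shape,
       geometry = spindle_geometry(geometry$theta0_deg,
                                   shape$thetak_model_deg,
                                   geometry$L_um, shape$hk_model_um,
                                   geometry$xk_um))
}

# memoised solve of the reference (measured) geometry, reused across tests
.fixture_env <- new.env(parent = emptyenv())
reference_solution <- function() {
  if (is.null(.fixture_env$fb))
    .fixture_env$fb <- solve_force_balance(ref_geometry(), ref_architecture())
  .fixture_env$fb
}
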