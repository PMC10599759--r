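test_that("bound-limited chain maximum: all fluxes at the uptake cap", {
  sol <- solve_fba(chain_model(10))
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$v), c(10, 10, 10), tolerance = 1e-9)
  expect_equal(sol$z, 10, tolerance = 1e-9)
  # reduced cost sits on the binding uptake bound, interior reactions 0
  expect_equal(unname(sol$delta), c(1, 0, 0), tolerance = 1e-9)
})

test_that("infeasible and unbounded formulations are flagged", {
  m <- chain_model()
  m$lower_bounds[1] <- 0; m$upper_bounds[1] <- 0   # no uptake
  m$lower_bounds[3] <- 5                            # but forced export
  expect_identical(solve_fba(m)$status, "infeasible")

  u <- metabolic_model("m1", c("in", "out"), rbind(c(1, -1)),
                       c(0, 0), c(Inf, Inf), c(0, 1))
  expect_identical(solve_fba(u)$status, "unbounded")
})

test_that("LP optimum equals brute-force vertex enumeration on small models", {
  for (seed in 1:12) {
    model <- random_lp_model(seed)
    sol <- solve_fba(model)
    oracle <- enumerate_lp_optimum(model)
    if (!is.finite(oracle$z)) {
      expect_identical(sol$status, "infeasible", label = paste("seed", seed))
      next
    }
    expect_identical(sol$status, "optimal")
    expect_equal(sol$z, oracle$z, tolerance = 1e-6,
                 label = paste("objective, seed", seed))
    expect_lt(max(abs(model$S %*% sol$v)), 1e-6)
  }
})

test_that("reduced costs match the finite-difference bound perturbation", {
  models <- c(list(chain_model()), lapply(21:28, random_lp_model))
  for (i in seq_along(models)) {
    model <- models[[i]]
    sol <- solve_fba(model)
    if (sol$status != "optimal") next
    for (j in seq_along(model$reaction_ids)) {
      at_bound <- abs(sol$v[j] - model$upper_bounds[j]) < 1e-7 ||
        abs(sol$v[j] - model$lower_bounds[j]) < 1e-7
      if (!at_bound) {
        expect_lt(abs(sol$delta[j]), 1e-6)
      } else {
        expect_equal(unname(sol$delta[j]), fd_reduced_cost(model, j),
                     tolerance = 1e-4,
                     label = sprintf("model %d reaction %d", i, j))
      }
    }
  }
})

test_that("strong duality holds: z equals the dual bound objective", {
  for (seed in c(2, 7, 31)) {
    model <- random_lp_model(seed)
    sol <- solve_fba(model)
    if (sol$status != "optimal") next
    p <- pmax(sol$delta, 0); q <- pmax(-sol$delta, 0)
    dual_obj <- sum(model$upper_bounds * p) - sum(model$lower_bounds * q)
    expect_equal(sol$z, dual_obj, tolerance = 1e-6)
  }
})

test_that("sensitivity set extraction applies the tolerance threshold", {
  sol <- structure(list(status = "optimal",
                        delta = c(a = 0, b = 1e-12, c = 0.3)),
                   class = "FBASolution")
  out <- extract_sensitivity_set(sol, tolerance = 1e-9)
  expect_identical(out$s, "c")
  expect_identical(out$k, 1L)
  none <- structure(list(status = "optimal", delta = c(a = 0, b = 0)),
                    class = "FBASolution")
  expect_identical(extract_sensitivity_set(none)$k, 0L)
  bad <- structure(list(status = "infeasible"), class = "FBASolution")
  expect_error(extract_sensitivity_set(bad), "optimal")
})

test_that("sensitivity set on the chain equals the bound-active oracle set", {
  model <- chain_model()
  sol <- solve_fba(model)
  s <- extract_sensitivity_set(sol)$s
  fd <- vapply(seq_along(model$reaction_ids),
               function(j) fd_reduced_cost(model, j), numeric(1))
  expect_setequal(s, model$reaction_ids[abs(fd) > 1e-6])
})

test_that("astrocytic glycolysis fitting matches a grid-scan oracle", {
  # astro: glucose -> 2 extracellular lactate; neuron: lactate -> 1 ATP
  m <- metabolic_model(
    metabolite_ids = c("glc_a", "lac_e", "lac_n", "atp_n"),
    reaction_ids = c("GLCt_a", "GLYC_a", "LACt_n", "ATPS_n", "ATPuse_n"),
    S = rbind(c(1, -1, 0, 0, 0),
              c(0, 2, -1, 0, 0),
              c(0, 0, 1, -1, 0),
              c(0, 0, 0, 1, -1)),
    lower_bounds = rep(0, 5), upper_bounds = c(10, 100, 100, 100, 100),
    objective_coefficients = c(0, 0, 0, 0, 1)
  )
  fit <- fit_astrocytic_glycolysis(m, neuronal_atp_demand = 4)
  expect_equal(fit$bound, 2, tolerance = 1e-4)
  grid <- seq(0, 5, by = 0.005)
  achieved <- vapply(grid, function(b) {
    mm <- m; mm$upper_bounds[1] <- b
    neuronal_atp_production(mm, solve_fba(mm)$v)
  }, numeric(1))
  expect_equal(fit$bound, min(grid[achieved >= 4]), tolerance = 5e-3)
  # null demand needs no astrocytic glycolysis
  expect_equal(fit_astrocytic_glycolysis(m, 0)$bound, 0)
  # monotone in the demand
  b1 <- fit_astrocytic_glycolysis(m, 1)$bound
  b2 <- fit_astrocytic_glycolysis(m, 3)$bound
  expect_lte(b1, b2)
  expect_error(fit_astrocytic_glycolysis(m, 1e6), "unreachable")
})

test_that("phenotypic phase plane: shape, monotonicity and substrate slope", {
  m <- metabolic_model(
    metabolite_ids = c("o2", "glc"),
    reaction_ids = c("up_o2", "up_glc", "burn", "spill_o2", "spill_glc"),
    S = rbind(c(1, 0, -1, -1, 0), c(0, 1, -1, 0, -1)),
    lower_bounds = rep(0, 5), upper_bounds = c(10, 10, 100, 100, 100),
    objective_coefficients = c(0, 0, 1, 0, 0)
  )
  o2r <- c(1, 2, 3); glcr <- c(1, 2)
  grid <- compute_phpp(m, o2r, glcr, oxygen_rxn = "up_o2",
                       glucose_rxn = "up_glc")
  expect_identical(dim(grid$Phpp), c(3L, 2L, 5L))
  expect_true(all(grid$feasible))
  # z = min(o2, glc): non-decreasing along each axis, non-zero slope
  expect_true(all(apply(grid$objective, 1, diff) >= -1e-9))
  expect_true(all(apply(grid$objective, 2, diff) >= -1e-9))
  expect_gt(abs(grid$objective[3, 2] - grid$objective[1, 2]), 1e-9)
  expect_equal(grid$objective, outer(o2r, glcr, pmin), tolerance = 1e-8)
  expect_error(compute_phpp(m, c(1, 99), glcr, "up_o2", "up_glc"),
               "outside")
})

test_that("the synthetic model couples sodium efflux to pump ATP 3:1", {
  model <- generate_toy_network(synthetic_spec(seed = 1))
  sol <- solve_fba(model)
  expect_identical(sol$status, "optimal")
  expect_gt(sol$z, 0)
  na_row <- match("na_e", model$metabolite_ids)
  nak <- match("NAK_n", model$reaction_ids)
  efflux <- model$S[na_row, nak] * sol$v[nak]
  expect_equal(unname(efflux), 3 * unname(sol$v[nak]), tolerance = 1e-9)
  expect_lt(max(abs(model$S %*% sol$v)), 1e-6)
})
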