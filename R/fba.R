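#' Physiological flux constants for the stimulated neuron-astrocyte system
#'
#' Measured and derived flux constraints (all uM/s unless noted) used to
#' parameterize the coupled neurotransmission objective: the post-stimulus
#' sodium efflux, the 3 Na : 1 ATP stoichiometry of the Na/K-ATPase, the
#' housekeeping ATP demand, the resting neuronal glucose consumption and its
#' stimulation fold change, the oxidative ATP yield per glucose, and the
#' astrocytic oxygen uptake in co-culture. Derived entries (`na_pump_atp`,
#' `stimulated_glycolysis`, `glycolytic_atp`, `total_atp_demand`) are computed
#' from the primary constants at call time.
#'
#' @return named list of constants.
#' @export
#' @examples
#' fba_constants()$total_atp_demand
fba_constants <- function() {
  k <- list(
    sodium_efflux = 350,        # uM/s Na+ extruded after stimulation
    na_per_atp = 3,             # Na+ ions exported per ATP hydrolyzed
    housekeeping_atp = 38,      # uM/s basal neuronal ATP demand
    resting_glucose = 0.9,      # uM/s neuronal glucose uptake at rest
    stimulation_fold = 2.353,   # fold increase of glycolysis on stimulation
    atp_per_glucose = 31,       # ATP yield per glucose, full oxidation
    astro_o2_uptake = 0.01666   # uM/s astrocytic oxygen uptake (co-culture)
  )
  k$na_pump_atp <- k$sodium_efflux / k$na_per_atp
  k$stimulated_glycolysis <- k$resting_glucose * k$stimulation_fold
  k$glycolytic_atp <- k$stimulated_glycolysis * k$atp_per_glucose
  k$total_atp_demand <- k$housekeeping_atp + k$na_pump_atp
  k
}

#' Solve flux balance analysis
#'
#' Maximizes the metabolic objective `z = c'v` subject to steady-state mass
#' balance `S v = 0` and flux bounds `lb <= v <= ub`, and reports the
#' reduced-cost vector `delta` (the LP dual sensitivity `dz/dv_i`). Sign
#' convention: `delta_i > 0` means relaxing an active bound on `v_i` upward
#' increases the optimum.
#'
#' The LP is solved by [lp_bounded()], a bounded-variable two-phase revised
#' simplex whose optimal basis yields the exact dual vector `y`, from which
#' `delta = c - S'y` (zero on basic/interior fluxes up to round-off).
#'
#' @param model a [metabolic_model()].
#' @return an `FBASolution`: list with `status` (`"optimal"`, `"infeasible"`
#'   or `"unbounded"`), `v` (named flux vector), `z` (objective value) and
#'   `delta` (named reduced costs).
#' @export
solve_fba <- function(model) {
  validate_model(model)
  n <- length(model$reaction_ids)
  sol <- lp_bounded(model$objective_coefficients, model$S,
                    rep(0, nrow(model$S)),
                    model$lower_bounds, model$upper_bounds, maximize = TRUE)
  empty <- stats::setNames(rep(NA_real_, n), model$reaction_ids)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, v = empty, z = NA_real_,
                          delta = empty), class = "FBASolution"))
  }
  v <- stats::setNames(sol$x, model$reaction_ids)
  delta <- stats::setNames(sol$reduced_costs, model$reaction_ids)
  structure(list(status = "optimal", v = v, z = sol$value, delta = delta,
                 dual = sol$duals), class = "FBASolution")
}

#' @export
print.FBASolution <- function(x, ...) {
  cat(sprintf("FBASolution: status=%s", x$status))
  if (x$status == "optimal") {
    cat(sprintf(", z=%.6g, %d/%d reactions with |reduced cost|>1e-9",
                x$z, sum(abs(x$delta) > 1e-9), length(x$v)))
  }
  cat("\n")
  invisible(x)
}

#' Extract the sensitivity set of an FBA solution
#'
#' The sensitivity set `s` is the group of reactions with a non-zero reduced
#' cost at the optimum: the reactions whose (active) constraints the optimal
#' objective responds to, acting as the interface through which fast
#' perturbations reach the optimal state.
#'
#' @param solution an optimal [solve_fba()] result.
#' @param tolerance absolute reduced-cost threshold (default `1e-9`).
#' @return list with `s` (reaction ids) and `k = length(s)`.
#' @export
extract_sensitivity_set <- function(solution, tolerance = 1e-9) {
  if (!identical(solution$status, "optimal")) {
    stop("sensitivity set requires an optimal FBA solution (status: ",
         solution$status, ")")
  }
  s <- names(solution$delta)[abs(solution$delta) > tolerance]
  list(s = s, k = length(s))
}

#' Neuronal ATP production rate at a flux state
#'
#' Sums ATP synthesis (positive stoichiometry times flux) over neuronal ATP
#' species; used as the demand criterion when fitting the astrocytic
#' glycolytic bound.
#'
#' @param model a [metabolic_model()].
#' @param v flux vector from [solve_fba()].
#' @param atp_pattern regular expression identifying neuronal ATP
#'   metabolite(s).
#' @return total neuronal ATP production (uM/s).
#' @export
neuronal_atp_production <- function(model, v, atp_pattern = "^atp_n$") {
  rows <- grep(atp_pattern, model$metabolite_ids)
  if (!length(rows)) stop("no metabolite matches ", atp_pattern)
  prod <- model$S[rows, , drop = FALSE] %*% diag(as.numeric(v), length(v))
  sum(pmax(prod, 0))
}

#' Fit the astrocytic glycolytic bound to a neuronal ATP demand
#'
#' Finds, by bisection, the smallest astrocytic glucose-uptake bound at which
#' the FBA optimum delivers at least the requested neuronal ATP production
#' (the lactate supplied by astrocytic glycolysis closes the gap between the
#' neuronal glycolytic ATP supply and the total demand).
#'
#' @param model a [metabolic_model()].
#' @param neuronal_atp_demand target neuronal ATP production (uM/s, >= 0).
#' @param uptake_rxn id of the astrocytic glucose-uptake reaction whose upper
#'   bound is fitted.
#' @param demand_fn function(model, v) measuring delivered demand; defaults
#'   to [neuronal_atp_production()].
#' @param interval search interval for the bound.
#' @param tol bisection tolerance on the bound (default `1e-4`).
#' @return list with `bound` (fitted uptake bound), `model` (with the bound
#'   installed) and `achieved` (demand delivered at the fitted bound).
#' @export
fit_astrocytic_glycolysis <- function(model, neuronal_atp_demand,
                                      uptake_rxn = "GLCt_a",
                                      demand_fn = neuronal_atp_production,
                                      interval = c(0, 100), tol = 1e-4) {
  stopifnot(neuronal_atp_demand >= 0)
  j <- match(uptake_rxn, model$reaction_ids)
  if (is.na(j)) stop("unknown uptake reaction: ", uptake_rxn)
  eval_at <- function(b) {
    m <- model
    m$upper_bounds[j] <- b
    m$lower_bounds[j] <- min(m$lower_bounds[j], b)
    sol <- solve_fba(m)
    if (!identical(sol$status, "optimal")) return(-Inf)
    demand_fn(m, sol$v)
  }
  lo <- interval[1]; hi <- interval[2]
  if (eval_at(lo) >= neuronal_atp_demand) {
    fitted <- lo
  } else {
    top <- eval_at(hi)
    if (top < neuronal_atp_demand) {
      stop(sprintf(
        "demand %.4g unreachable: maximal achievable at bound %.4g is %.4g",
        neuronal_atp_demand, hi, top))
    }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (eval_at(mid) >= neuronal_atp_demand) hi <- mid else lo <- mid
    }
    fitted <- hi
  }
  out <- model
  out$upper_bounds[j] <- fitted
  out$lower_bounds[j] <- min(out$lower_bounds[j], fitted)
  list(bound = fitted, model = out, achieved = eval_at(fitted))
}

#' Phenotypic phase plane scan
#'
#' Scans a grid of oxygen x glucose uptake rates; at each grid point both the
#' lower and upper bound of the designated uptake reactions are fixed to the
#' axis value (paired inequalities collapse to equality) and the FBA is
#' re-solved. The full optimal flux vector is stored per grid cell.
#'
#' @param model a [metabolic_model()].
#' @param oxygen_rates,glucose_rates numeric axes of uptake rates, expressed
#'   in the model's own sign convention (uptake via an exchange reaction is a
#'   negative flux; uptake via a transporter is positive).
#' @param oxygen_rxn,glucose_rxn reaction ids whose bounds are scanned.
#' @return a `PhPPGrid`: list with the axes, `Phpp` (array
#'   `n_oxygen x n_glucose x n_reactions`), `objective` matrix and `feasible`
#'   logical matrix.
#' @export
compute_phpp <- function(model, oxygen_rates, glucose_rates,
                         oxygen_rxn = "O2t_n", glucose_rxn = "GLCt_n") {
  stopifnot(length(oxygen_rates) > 0, length(glucose_rates) > 0)
  jo <- match(oxygen_rxn, model$reaction_ids)
  jg <- match(glucose_rxn, model$reaction_ids)
  if (is.na(jo) || is.na(jg)) stop("unknown uptake reaction id")
  chk <- function(rates, j, what) {
    if (any(rates < model$lower_bounds[j] - 1e-12) ||
        any(rates > model$upper_bounds[j] + 1e-12)) {
      stop(what, " axis values fall outside the model's global bounds")
    }
  }
  chk(oxygen_rates, jo, "oxygen"); chk(glucose_rates, jg, "glucose")
  n <- length(model$reaction_ids)
  Phpp <- array(NA_real_,
                dim = c(length(oxygen_rates), length(glucose_rates), n),
                dimnames = list(NULL, NULL, model$reaction_ids))
  objective <- matrix(NA_real_, length(oxygen_rates), length(glucose_rates))
  feasible <- matrix(FALSE, length(oxygen_rates), length(glucose_rates))
  for (i in seq_along(oxygen_rates)) {
    for (j in seq_along(glucose_rates)) {
      m <- model
      m$lower_bounds[jo] <- m$upper_bounds[jo] <- oxygen_rates[i]
      m$lower_bounds[jg] <- m$upper_bounds[jg] <- glucose_rates[j]
      sol <- solve_fba(m)
      if (identical(sol$status, "optimal")) {
        Phpp[i, j, ] <- sol$v
        objective[i, j] <- sol$z
        feasible[i, j] <- TRUE
      }
    }
  }
  structure(list(oxygen_rates = oxygen_rates, glucose_rates = glucose_rates,
                 Phpp = Phpp, objective = objective, feasible = feasible),
            class = "PhPPGrid")
}

#' Reproduce the published FBA read-outs on an external two-cell model
#'
#' Given a locally available copy of the genome-scale neuron-astrocyte
#' reconstruction, installs the measured flux constraints
#' ([fba_constants()]), fits the astrocytic glycolytic bound to the total
#' neuronal ATP demand and reports the headline fluxes (neuronal sodium
#' efflux, astrocytic lactate efflux, vesicular glutamate export, ATP yield
#' per glucose). The reconstruction is not redistributable with this package
#' and must be supplied by the user.
#'
#' @param model_path path to the reconstruction (JSON or SBML dialect read by
#'   [read_model()]).
#' @param rxn_ids named list mapping the roles `sodium_efflux`,
#'   `lactate_efflux`, `glutamate_export`, `neuron_glucose`,
#'   `astro_glucose`, `astro_o2` to reaction ids in that model.
#' @return named list of fluxes (uM/s) plus `atp_per_glucose`.
#' @export
reproduce_published_fba <- function(model_path, rxn_ids) {
  model <- read_model(model_path)
  k <- fba_constants()
  setb <- function(m, id, lb, ub) {
    j <- match(id, m$reaction_ids)
    if (is.na(j)) stop("reaction not found in external model: ", id)
    m$lower_bounds[j] <- lb; m$upper_bounds[j] <- ub
    m
  }
  model <- setb(model, rxn_ids$neuron_glucose, 0, k$stimulated_glycolysis)
  model <- setb(model, rxn_ids$astro_o2, 0, k$astro_o2_uptake)
  fit <- fit_astrocytic_glycolysis(model, k$total_atp_demand,
                                   uptake_rxn = rxn_ids$astro_glucose)
  sol <- solve_fba(fit$model)
  glc <- sol$v[rxn_ids$neuron_glucose] + fit$bound
  list(sodium_efflux = unname(sol$v[rxn_ids$sodium_efflux]),
       lactate_efflux = unname(sol$v[rxn_ids$lactate_efflux]),
       glutamate_export = unname(sol$v[rxn_ids$glutamate_export]),
       atp_per_glucose = neuronal_atp_production(fit$model, sol$v) / glc,
       fitted_astro_glucose_bound = fit$bound)
}
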