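#' Solve the steady-state flux-balance linear program
#'
#' Maximizes (or minimizes) the flux through the model's objective
#' reaction subject to the steady-state constraint `S v = 0` and the
#' reaction bounds. Infinite bounds are capped at `unbounded_cap`
#' (the conventional "unlimited" flux). The optimal objective value is
#' unique; the flux vector may not be when the optimum is degenerate, in
#' which case the solution carries `degenerate = TRUE`.
#'
#' @param model a valid `mf_model` with a resolvable `objective_id`
#' @param direction `"maximize"` (default) or `"minimize"`
#' @param unbounded_cap replacement for infinite bounds, default 99999
#' @param tol solver pivot/feasibility tolerance
#' @return an `mf_flux_solution`: list with `status` (`"optimal"`,
#'   `"infeasible"` or `"unbounded"`), `objective_value`, `fluxes`
#'   (named by reaction id; `NULL` unless optimal), `degenerate`
#' @examples
#' m <- stoichiometric_model(
#'   list(metabolite("A"), metabolite("B")),
#'   list(reaction("EX_A", c(A = 1), 0, 5, subsystem = "exchange"),
#'        reaction("R1", c(A = -1, B = 1), 0, 99999),
#'        reaction("DM_B", c(B = -1), 0, 99999, subsystem = "demand")),
#'   objective_id = "DM_B")
#' solve_fba(m)$objective_value  # 5: the uptake bound is the bottleneck
#' @export
solve_fba <- function(model, direction = c("maximize", "minimize"),
                      unbounded_cap = 99999, tol = 1e-9) {
  direction <- match.arg(direction)
  rep <- validate_model(model)
  rep <- rep[rep$type != "orphan_metabolite", , drop = FALSE]
  if (nrow(rep) > 0L)
    stop("invalid model: ", rep$type[1L], " (", rep$id[1L], ")")
  if (is.na(model$objective_id))
    stop("model has no objective reaction")
  S <- assemble_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  lb[!is.finite(lb)] <- -unbounded_cap
  ub[!is.finite(ub)] <- unbounded_cap
  obj <- as.numeric(colnames(S) == model$objective_id)
  res <- .lp_box(obj, S, lb, ub, maximize = direction == "maximize",
                 tol = tol)
  if (res$status %in% c("maxiter", "singular"))
    stop("LP solver failed to converge (", res$status, ")")
  fluxes <- NULL
  if (res$status == "optimal") {
    fluxes <- setNames(res$x, colnames(S))
    resid <- max(abs(S %*% res$x))
    if (resid > 1e-6)
      warning("steady-state residual ", format(resid), " exceeds 1e-6")
  }
  structure(list(status = res$status,
                 objective_value = if (res$status == "optimal")
                   res$objective else NA_real_,
                 fluxes = fluxes,
                 degenerate = isTRUE(res$degenerate)),
            class = "mf_flux_solution")
}

#' @export
print.mf_flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status)
  if (x$status == "optimal") {
    cat(sprintf(", objective %.6g", x$objective_value))
    if (x$degenerate) cat(" (degenerate optimum: flux vector not unique)")
  }
  cat("\n")
  invisible(x)
}

#' Flux differences between two optimal solutions
#'
#' Per-reaction flux change of `sol` relative to `control`. Both
#' solutions must be optimal and cover the same reaction set. Note that
#' at a degenerate optimum the flux vector itself is solver-dependent,
#' so differences of non-objective fluxes should be read qualitatively.
#'
#' @param sol,control optimal `mf_flux_solution` objects
#' @return named numeric vector, `sol$fluxes - control$fluxes`
#' @export
flux_difference <- function(sol, control) {
  stopifnot(inherits(sol, "mf_flux_solution"),
            inherits(control, "mf_flux_solution"))
  if (sol$status != "optimal" || control$status != "optimal")
    stop("both solutions must be optimal")
  if (!setequal(names(sol$fluxes), names(control$fluxes)))
    stop("solutions cover different reaction sets")
  sol$fluxes - control$fluxes[names(sol$fluxes)]
}

#' Export a flux solution (or a delta vector) as two-column TSV
#'
#' @param fluxes an `mf_flux_solution` or a named numeric vector
#' @param path output file
#' @return the path, invisibly
#' @export
export_fluxes_tsv <- function(fluxes, path) {
  if (inherits(fluxes, "mf_flux_solution")) fluxes <- fluxes$fluxes
  write.table(data.frame(reaction = names(fluxes), flux = fluxes),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Brute-force vertex enumeration oracle for small models
#'
#' Independent check of [solve_fba()]: enumerates every basic solution
#' of the polytope `{S v = 0, lb <= v <= ub}` (all choices of basic
#' column subsets at the rank of S, with nonbasic variables on either
#' bound), keeps the feasible ones, and returns the best objective
#' value. Exponential in the reaction count, hence refused above
#' `max_reactions`.
#'
#' @param model a valid `mf_model` with at most `max_reactions` reactions
#'   and finite bounds
#' @param direction `"maximize"` or `"minimize"`
#' @param max_reactions refusal cap, default 10
#' @param tol feasibility tolerance for candidate vertices
#' @return list with `status` (`"optimal"` or `"infeasible"`) and
#'   `objective_value`
#' @export
brute_force_vertex_optimum <- function(model,
                                       direction = c("maximize", "minimize"),
                                       max_reactions = 10L, tol = 1e-7) {
  direction <- match.arg(direction)
  S <- assemble_matrix(model)
  n <- ncol(S)
  if (n > max_reactions)
    stop("refusing brute force above ", max_reactions, " reactions")
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("brute force requires finite bounds")
  obj <- as.numeric(colnames(S) == model$objective_id)
  r <- qr(S)$rank
  best <- if (direction == "maximize") -Inf else Inf
  better <- if (direction == "maximize") `>` else `<`
  feasible <- FALSE
  check <- function(v) {
    if (max(abs(S %*% v)) > tol * (1 + max(abs(v)))) return()
    if (any(v < lb - tol) || any(v > ub + tol)) return()
    feasible <<- TRUE
    val <- sum(obj * v)
    if (better(val, best)) best <<- val
  }
  if (r == 0L) {
    # no coupling: each variable sits freely in its box
    check(if (direction == "maximize") ifelse(obj > 0, ub, lb)
          else ifelse(obj > 0, lb, ub))
  } else {
    basis_sets <- combn(n, r, simplify = FALSE)
    grid <- if (n == r) matrix(FALSE, 1L, 0L)
            else as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n - r)))
    for (bs in basis_sets) {
      B <- S[, bs, drop = FALSE]
      if (qr(B)$rank < r) next
      nb <- setdiff(seq_len(n), bs)
      Bq <- qr(B)
      for (g in seq_len(nrow(grid))) {
        vn <- ifelse(grid[g, ], ub[nb], lb[nb])
        rhs <- -S[, nb, drop = FALSE] %*% vn
        vb <- tryCatch(qr.coef(Bq, rhs), error = function(e) NULL)
        if (is.null(vb) || anyNA(vb)) next
        v <- numeric(n)
        v[bs] <- vb
        v[nb] <- vn
        check(v)
      }
    }
  }
  if (!feasible)
    list(status = "infeasible", objective_value = NA_real_)
  else
    list(status = "optimal", objective_value = best)
}
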