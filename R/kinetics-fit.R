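#' Fit the negative exponential digestion model to one time course
#'
#' Least-squares fit of \eqn{D(t) = a + b (1 - e^{-c t})} to percent
#' digested over incubation time, with the physical constraints
#' `a, b >= 0`, `a + b <= 100 + slack` and `c in [0, c_max]`. Because the
#' earliest in-situ observation is typically 24 h (no 0-h bag), `a` is
#' weakly identified and local minima are a real hazard; the optimiser
#' therefore profiles `c` on a dense grid — for fixed `c` the model is
#' linear in `(a, b)` and solved in closed form under the constraints —
#' and then polishes the best candidates with bounded quasi-Newton
#' iterations started from several rate values. Equal-RSS optima are
#' resolved towards the smallest `c`.
#'
#' @param time_h incubation times (hours), strictly increasing, length >= 3.
#' @param digested_pct percent of the fiber fraction digested at each time.
#' @param ab_max upper bound on `a + b` (default 105: pools in % with
#'   slack for noise).
#' @param c_max upper bound on the fractional rate (h^-1).
#' @param unit optional named list identifying the unit; carried through.
#' @return object of class `kinetics_fit`: list with `a`, `b`, `c`,
#'   `ext120` (predicted digestion at 120 h, always equal to
#'   `predict_digestion(fit, 120)`), `rss`, `converged`, `degenerate`,
#'   `n_obs` and `unit`.
#' @export
#' @examples
#' t <- c(24, 36, 48, 72, 96, 120)
#' d <- 5 + 60 * (1 - exp(-0.02 * t))
#' fit_digestion_curve(t, d)
fit_digestion_curve <- function(time_h, digested_pct, ab_max = 105,
                                c_max = 0.5, unit = NULL) {
  t <- as.numeric(time_h)
  d <- as.numeric(digested_pct)
  if (length(t) != length(d)) stop_rf("time and digestion vectors differ in length")
  if (length(t) < 3L) stop_rf("at least 3 observations are required")
  if (any(!is.finite(t)) || any(!is.finite(d))) stop_rf("non-finite observations")
  if (any(t <= 0) || is.unsorted(t, strictly = TRUE))
    stop_rf("times must be positive and strictly increasing")
  if (any(d < -1e-9) || any(d > 100 + 1e-9))
    stop_rf("digested percentages must lie in [0, 100]")

  if (max(d) - min(d) < 1e-12) {
    # flat curve: rate unidentifiable, report the mean as instant pool
    fit <- new_kinetics_fit(mean(d), 0, 0, rss = sum((d - mean(d))^2),
                            converged = TRUE, degenerate = TRUE,
                            n_obs = length(t), unit = unit)
    return(fit)
  }

  rss_of <- function(p) sum((d - (p[1] + p[2] * (1 - exp(-p[3] * t))))^2)

  # profile stage: constrained linear solve of (a, b) on a c grid
  c_grid <- sort(unique(c(seq(0, c_max, length.out = 201L),
                          c(0.005, 0.02, 0.05))))
  prof <- t(vapply(c_grid, function(cc) {
    ab <- solve_ab(t, d, cc, ab_max)
    c(ab, rss = sum((d - (ab[1] + ab[2] * (1 - exp(-cc * t))))^2))
  }, numeric(3)))
  ord <- order(prof[, "rss"], c_grid)  # ties -> smallest c
  starts <- lapply(ord[seq_len(min(3L, nrow(prof)))], function(i)
    c(prof[i, 1L], prof[i, 2L], c_grid[i]))
  # prescribed multi-start rate values guard the profile resolution
  for (c0 in c(0.005, 0.02, 0.05)) {
    ab <- solve_ab(t, d, c0, ab_max)
    starts <- c(starts, list(c(ab, c0)))
  }
  starts <- c(starts, list(c(max(min(d), 0), max(d) - min(d), 0.02)))

  # parameters live on very different scales (% pools vs an h^-1 rate);
  # parscale keeps the quasi-Newton line search sane
  ctrl <- list(factr = 1e1, maxit = 1000L, parscale = c(50, 50, 0.02))
  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- tryCatch(
      optim(pmin(pmax(s, c(0, 0, 0)), c(ab_max, ab_max, c_max)), rss_of,
            method = "L-BFGS-B", lower = c(0, 0, 0),
            upper = c(ab_max, ab_max, c_max), control = ctrl),
      error = function(e) NULL)
    if (is.null(o)) next
    # simplex polish sharpens past any stalled line search, then a final
    # bounded step restores feasibility if the polish drifted out
    o2 <- optim(o$par, rss_of, control = list(reltol = 1e-15, maxit = 2000L))
    if (o2$value < o$value &&
        all(o2$par >= -1e-12) && o2$par[3] <= c_max + 1e-12) {
      o$par <- pmin(pmax(o2$par, 0), c(ab_max, ab_max, c_max))
      o$value <- rss_of(o$par)
      o$convergence <- 0L
    }
    cand <- o$par
    if (cand[1] + cand[2] > ab_max + 1e-9) {
      # re-solve on the boundary a + b = ab_max (rare with % data)
      ob <- optim(c(min(cand[1], ab_max), cand[3]), function(q)
        rss_of(c(q[1], ab_max - q[1], q[2])), method = "L-BFGS-B",
        lower = c(0, 0), upper = c(ab_max, c_max))
      cand <- c(ob$par[1], ab_max - ob$par[1], ob$par[2])
      o$value <- ob$value
    }
    if (is.null(best) || o$value < best$value - 1e-10 ||
        (abs(o$value - best$value) <= 1e-10 && cand[3] < best$par[3])) {
      best <- list(par = cand, value = o$value)
      conv <- conv || o$convergence == 0
    }
  }
  if (is.null(best)) stop_rf("digestion-curve fit failed on all starts")
  new_kinetics_fit(best$par[1], best$par[2], best$par[3], rss = best$value,
                   converged = conv, degenerate = FALSE,
                   n_obs = length(t), unit = unit)
}

# constrained least squares for (a, b) at fixed c: the model is linear,
# D = a + b k with k = 1 - exp(-c t); solve unconstrained then project
# onto a, b >= 0, a + b <= ab_max by checking each active boundary
solve_ab <- function(t, d, cc, ab_max) {
  k <- 1 - exp(-cc * t)
  cand <- list()
  if (var(k) > 1e-18) {
    f <- lm.fit(cbind(1, k), d)$coefficients
    cand <- c(cand, list(f))
  }
  # boundary candidates: a = 0; b = 0; a + b = ab_max
  cand <- c(cand,
            list(c(0, if (sum(k^2) > 0) sum(d * k) / sum(k^2) else 0)),
            list(c(mean(d), 0)),
            {
              kk <- 1 - k
              c_ab <- if (sum(kk^2) > 0)
                sum((d - ab_max * k) * kk) / sum(kk^2) else 0
              list(c(c_ab, ab_max - c_ab))
            })
  best <- NULL
  for (p in cand) {
    p <- c(max(p[1], 0), max(p[2], 0))
    if (p[1] > ab_max) p[1] <- ab_max
    if (p[1] + p[2] > ab_max) p[2] <- ab_max - p[1]
    r <- sum((d - (p[1] + p[2] * k))^2)
    if (is.null(best) || r < best$r) best <- list(p = p, r = r)
  }
  c(a = best$p[1], b = best$p[2])
}

new_kinetics_fit <- function(a, b, c, rss, converged, degenerate, n_obs,
                             unit = NULL) {
  structure(list(a = unname(a), b = unname(b), c = unname(c),
                 ext120 = unname(a + b * (1 - exp(-120 * c))),
                 rss = unname(rss), converged = converged,
                 degenerate = degenerate, n_obs = n_obs, unit = unit),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf(
    "<kinetics_fit> a = %.3f %%, b = %.3f %%, c = %.5f /h, ext120 = %.2f %%%s\n",
    x$a, x$b, x$c, x$ext120,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Predict percent digested from a fitted curve
#'
#' Evaluates \eqn{a + b (1 - e^{-c t})}; at `t = 0` this is the instantly
#' disappearing intercept `a`, and as `t` grows it approaches the
#' asymptote `a + b` monotonically.
#'
#' @param fit a [fit_digestion_curve()] result (or any list with `a`,
#'   `b`, `c`).
#' @param t hours, `t >= 0` (vectorised).
#' @return percent digested at each `t`.
#' @export
predict_digestion <- function(fit, t) {
  if (any(t < 0)) stop_rf("negative incubation time")
  fit$a + fit$b * (1 - exp(-fit$c * t))
}

#' Assemble the six-response kinetics matrix
#'
#' Collects per-unit fits of the three fiber fractions into the response
#' matrix used by the association stages: one row per unit, columns
#' `(NDF rate, NDF ext120, cellulose rate, cellulose ext120,
#' hemicellulose rate, hemicellulose ext120)`. Fits missing for a
#' unit x fraction leave `NA` cells (flagged via the `missing` attribute)
#' without disturbing the rest of the row.
#'
#' @param fits list of `kinetics_fit` objects whose `unit` field carries
#'   `animal`, `season`, `diet`, `substrate` and `fraction`.
#' @return numeric matrix with rownames `animal_season_diet_substrate` and
#'   attribute `units` (data.frame of unit keys); attribute `missing`
#'   counts empty cells.
#' @export
summarize_kinetics <- function(fits) {
  fractions <- c("NDF", "cellulose", "hemicellulose")
  keys <- lapply(fits, function(f) {
    u <- f$unit
    if (is.null(u)) stop_rf("every fit needs a unit key")
    u
  })
  unit_id <- vapply(keys, function(u)
    paste(u$animal, u$season, u$diet, u$substrate, sep = "_"), character(1))
  frac <- vapply(keys, `[[`, character(1), "fraction")
  if (anyDuplicated(paste(unit_id, frac)))
    stop_rf("duplicate unit x fraction keys")
  if (!all(frac %in% fractions))
    stop_rf("unknown fraction label(s): ", paste(setdiff(frac, fractions),
                                                 collapse = ", "))
  uids <- unique(unit_id)
  cols <- as.vector(t(outer(fractions, c("rate", "ext120"), paste,
                            sep = "_")))
  Y <- matrix(NA_real_, length(uids), length(cols),
              dimnames = list(uids, cols))
  for (i in seq_along(fits)) {
    r <- match(unit_id[i], uids)
    Y[r, paste0(frac[i], "_rate")] <- fits[[i]]$c
    Y[r, paste0(frac[i], "_ext120")] <- fits[[i]]$ext120
  }
  units <- do.call(rbind, lapply(keys[match(uids, unit_id)], function(u)
    data.frame(animal = u$animal, season = u$season, diet = u$diet,
               substrate = u$substrate, stringsAsFactors = FALSE)))
  rownames(units) <- uids
  attr(Y, "units") <- units
  attr(Y, "missing") <- sum(is.na(Y))
  Y
}

#' Fit all time courses in a long table
#'
#' @param timecourses data.frame as written by [write_dataset()]:
#'   `animal, season, diet, substrate, fraction, time_h,
#'   fraction_digested_pct`.
#' @param ... passed to [fit_digestion_curve()].
#' @return list of `kinetics_fit` objects (one per unit x fraction).
#' @export
fit_all_kinetics <- function(timecourses, ...) {
  need <- c("animal", "season", "diet", "substrate", "fraction", "time_h",
            "fraction_digested_pct")
  if (!all(need %in% names(timecourses)))
    stop_rf("timecourses must have columns: ", paste(need, collapse = ", "))
  key <- interaction(timecourses$animal, timecourses$season,
                     timecourses$diet, timecourses$substrate,
                     timecourses$fraction, drop = TRUE)
  lapply(split(timecourses, key), function(g) {
    g <- g[order(g$time_h), ]
    fit_digestion_curve(g$time_h, g$fraction_digested_pct,
                        unit = list(animal = g$animal[1], season = g$season[1],
                                    diet = g$diet[1],
                                    substrate = g$substrate[1],
                                    fraction = g$fraction[1]), ...)
  })
}
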