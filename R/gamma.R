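# 2D gamma-index analysis restricted to a region of interest, plus an
# exhaustive brute-force oracle used to verify the optimized search.
#
# gamma(r) = min over evaluated positions e of
#   sqrt( |e - r|^2 / dta^2 + (D_eval(e) - D_ref(r))^2 / (pct% of D_norm)^2 )
# with D_norm the reference maximum over the ROI (global normalization) and
# D_eval interpolated on a sub-lattice of the plane spacing.

PASS_TOL <- 1e-9   # pass condition is gamma <= 1 + PASS_TOL

#' Gamma criteria
#'
#' @param dose_pct dose-difference criterion, percent of the normalization
#'   dose (the reference-plane maximum over the ROI).
#' @param dta_mm distance-to-agreement criterion, mm.
#' @param normalization only `"max_reference_plane"` (global) is provided.
#' @param search_radius_mm spatial search cutoff; gamma values are capped at
#'   `search_radius_mm / dta_mm`.
#' @param interp_step_mm target step of the evaluated-dose interpolation
#'   sub-lattice; quantized to an integer divisor of the plane spacing.
#' @return an object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_pct = 3, dta_mm = 3,
                           normalization = "max_reference_plane",
                           search_radius_mm = 3 * dta_mm,
                           interp_step_mm = dta_mm / 10) {
  stopifnot(dose_pct > 0, dta_mm > 0, search_radius_mm >= dta_mm,
            interp_step_mm > 0,
            identical(normalization, "max_reference_plane"))
  structure(list(dose_pct = dose_pct, dta_mm = dta_mm,
                 normalization = normalization,
                 search_radius_mm = search_radius_mm,
                 interp_step_mm = interp_step_mm),
            class = "gamma_criteria")
}

#' @export
format.gamma_criteria <- function(x, ...) {
  sprintf("%g%%/%g mm", x$dose_pct, x$dta_mm)
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat("<gamma_criteria>", format(x), "\n"); invisible(x)
}

#' Gamma analysis result
#'
#' @param gamma `nu x nv` gamma map (`NA` outside the ROI).
#' @param pass_mask logical matrix: ROI pixels with `gamma <= 1` (within a
#'   1e-9 floating tolerance).
#' @param criteria the [gamma_criteria()] used.
#' @param normalization_dose Gy.
#' @param roi the [ciao_mask_record()] actually analyzed (after any
#'   neighborhood-validity drops).
#' @return an object of class `gamma_result` with fields `gamma`,
#'   `pass_mask`, `pass_rate` (percent), `criteria`, `normalization_dose`,
#'   `roi_pixel_count`.
#' @export
gamma_result <- function(gamma, pass_mask, criteria, normalization_dose, roi) {
  n_roi <- sum(roi$mask)
  structure(list(gamma = gamma, pass_mask = pass_mask,
                 pass_rate = 100 * sum(pass_mask) / n_roi,
                 criteria = criteria,
                 normalization_dose = normalization_dose,
                 roi_pixel_count = n_roi, roi = roi),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> %s: pass rate %.1f%% over %d ROI pixels (norm %.4g Gy, median gamma %.3f)\n",
              format(x$criteria), x$pass_rate, x$roi_pixel_count,
              x$normalization_dose, stats::median(x$gamma, na.rm = TRUE)))
  invisible(x)
}

#' Image of a gamma map
#'
#' @param x a [gamma_result()].
#' @param ... passed to [graphics::image()].
#' @export
plot.gamma_result <- function(x, ...) {
  g <- pmin(x$gamma, 2)
  graphics::image(g, useRaster = TRUE, asp = ncol(g) / nrow(g),
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = sprintf("gamma %s (pass %.1f%%)", format(x$criteria),
                                 x$pass_rate), ...)
  invisible(x)
}

# bilinear upsample of a plane image by integer factor k; invalid coarse
# nodes poison every fine cell they contribute to with nonzero weight
.upsample_plane <- function(values, valid, k) {
  if (k == 1L) {
    out <- values; out[!valid] <- NA_real_
    return(out)
  }
  n1 <- nrow(values); n2 <- ncol(values)
  f1 <- (seq_len((n1 - 1L) * k + 1L) - 1) / k + 1
  f2 <- (seq_len((n2 - 1L) * k + 1L) - 1) / k + 1
  i0 <- pmin(floor(f1), n1 - 1L); w1 <- f1 - i0
  j0 <- pmin(floor(f2), n2 - 1L); w2 <- f2 - j0
  A <- values; A[!valid] <- 0
  R  <- A[i0, , drop = FALSE] * (1 - w1) + A[i0 + 1L, , drop = FALSE] * w1
  Rok <- (valid[i0, , drop = FALSE] | w1 == 1) &
         (valid[i0 + 1L, , drop = FALSE] | w1 == 0)
  E  <- t(t(R[, j0, drop = FALSE]) * (1 - w2) +
          t(R[, j0 + 1L, drop = FALSE]) * w2)
  Eok <- (Rok[, j0, drop = FALSE] | rep(w2 == 1, each = nrow(Rok))) &
         (Rok[, j0 + 1L, drop = FALSE] | rep(w2 == 0, each = nrow(Rok)))
  E[!Eok] <- NA_real_
  E
}

.gamma_prepare <- function(reference, evaluated, roi, criteria) {
  stopifnot(inherits(reference, "dose_plane"), inherits(evaluated, "dose_plane"),
            inherits(roi, "ciao_mask"), inherits(criteria, "gamma_criteria"))
  if (!isTRUE(all.equal(reference$spec, evaluated$spec)) ||
      !all(dim(roi$mask) == reference$spec$extent))
    stop("reference, evaluated and ROI must share one plane lattice")
  roi_m <- roi$mask & reference$valid
  if (!any(roi_m)) stop("empty ROI after removing invalid reference samples")
  dnorm_gy <- max(reference$values[roi_m])
  if (!is.finite(dnorm_gy) || dnorm_gy <= 0)
    stop("zero normalization dose over the ROI")
  spacing <- reference$spec$spacing
  k <- max(1L, as.integer(round(spacing / criteria$interp_step_mm)))
  list(roi_m = roi_m, dnorm = dnorm_gy,
       denom = criteria$dose_pct / 100 * dnorm_gy,
       spacing = spacing, k = k, step = spacing / k)
}

# drop ROI pixels whose search neighborhood is mostly invalid on the
# evaluated side (only computed when invalid samples exist at all)
.apply_neighborhood_rule <- function(roi_m, evaluated, criteria, spacing) {
  if (all(evaluated$valid)) return(roi_m)
  r_pix <- ceiling(criteria$search_radius_mm / spacing)
  offs <- expand.grid(di = -r_pix:r_pix, dj = -r_pix:r_pix)
  offs <- offs[(offs$di^2 + offs$dj^2) * spacing^2 <=
                 criteria$search_radius_mm^2 + 1e-9, ]
  idx <- which(roi_m, arr.ind = TRUE)
  d <- dim(roi_m)
  frac <- rep(0, nrow(idx)); n_off <- nrow(offs)
  for (o in seq_len(n_off)) {
    ii <- idx[, 1] + offs$di[o]; jj <- idx[, 2] + offs$dj[o]
    inb <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2]
    ok <- inb
    ok[inb] <- evaluated$valid[cbind(ii[inb], jj[inb])]
    frac <- frac + ok
  }
  drop_ <- frac / n_off < 0.5
  if (any(drop_)) {
    warning(sum(drop_), " ROI pixel(s) dropped: less than half of the gamma",
            " search neighborhood is valid")
    roi_m[idx[drop_, , drop = FALSE]] <- FALSE
  }
  roi_m
}

#' Gamma map over a region of interest
#'
#' Optimized exhaustive search: the evaluated dose is interpolated on a
#' sub-lattice of the plane spacing and candidate positions are visited in
#' shells of increasing distance, so a pixel is finalized as soon as the
#' spatial term alone exceeds its current best gamma (the result is exactly
#' the minimum over all candidates within the search radius). Gamma is
#' capped at `search_radius_mm / dta_mm`. ROI pixels with less than half of
#' their search neighborhood valid are dropped with a warning.
#'
#' @param reference reference [dose_plane()] (the shifted first-calculation
#'   plane; its ROI maximum defines the normalization dose).
#' @param evaluated evaluated [dose_plane()] (the second calculation).
#' @param roi a [ciao_mask_record()].
#' @param criteria a [gamma_criteria()].
#' @return a [gamma_result()].
#' @export
gamma_map <- function(reference, evaluated, roi, criteria = gamma_criteria()) {
  pre <- .gamma_prepare(reference, evaluated, roi, criteria)
  roi_m <- .apply_neighborhood_rule(pre$roi_m, evaluated, criteria, pre$spacing)
  if (!any(roi_m)) stop("empty ROI after the neighborhood-validity rule")
  k <- pre$k; step <- pre$step
  E <- .upsample_plane(evaluated$values, evaluated$valid, k)
  dE <- dim(E)
  r_f <- floor(criteria$search_radius_mm / step + 1e-9)
  cand <- expand.grid(di = -r_f:r_f, dj = -r_f:r_f)
  r2 <- (cand$di^2 + cand$dj^2) * step^2
  keep <- r2 <= criteria$search_radius_mm^2 + 1e-9
  cand <- cand[keep, ]; r2 <- r2[keep]
  ord <- order(r2)
  cand <- cand[ord, ]; r2 <- r2[ord]
  s2 <- r2 / criteria$dta_mm^2                     # spatial gamma^2 term
  shells <- split(seq_along(s2), s2)
  idx <- which(roi_m, arr.ind = TRUE)
  fi <- (idx[, 1] - 1L) * k + 1L
  fj <- (idx[, 2] - 1L) * k + 1L
  dref <- reference$values[idx]
  npix <- nrow(idx)
  best2 <- rep(Inf, npix)
  active <- seq_len(npix)
  for (sh in shells) {
    s2_sh <- s2[sh[1]]
    active <- active[best2[active] > s2_sh]
    if (length(active) == 0) break
    for (o in sh) {
      ii <- fi[active] + cand$di[o]
      jj <- fj[active] + cand$dj[o]
      inb <- ii >= 1L & ii <= dE[1] & jj >= 1L & jj <= dE[2]
      if (!any(inb)) next
      a_in <- active[inb]
      e <- E[cbind(ii[inb], jj[inb])]
      g2 <- s2_sh + ((e - dref[a_in]) / pre$denom)^2
      upd <- !is.na(g2) & g2 < best2[a_in]
      best2[a_in[upd]] <- g2[upd]
    }
  }
  cap <- criteria$search_radius_mm / criteria$dta_mm
  gvals <- pmin(sqrt(best2), cap)
  gmat <- matrix(NA_real_, nrow(roi_m), ncol(roi_m))
  gmat[idx] <- gvals
  pass <- matrix(FALSE, nrow(roi_m), ncol(roi_m))
  pass[idx] <- gvals <= 1 + PASS_TOL
  roi$mask <- roi_m
  gamma_result(gmat, pass, criteria, pre$dnorm, roi)
}

#' Brute-force gamma oracle
#'
#' Exhaustive minimization over every node of the evaluated interpolation
#' sub-lattice across the whole plane -- no search-radius shortcut, no
#' shell-wise early termination, no cap. Intended as an independent check of
#' [gamma_map()] on small planes; refuses inputs larger than 64 x 64.
#'
#' @inheritParams gamma_map
#' @param refine integer; multiplies the sub-lattice density (refine = 1
#'   reproduces [gamma_map()]'s candidate lattice, refine = 2 probes the
#'   discretization error).
#' @return a [gamma_result()].
#' @export
gamma_brute_force <- function(reference, evaluated, roi,
                              criteria = gamma_criteria(), refine = 1L) {
  pre <- .gamma_prepare(reference, evaluated, roi, criteria)
  if (any(reference$spec$extent > 64))
    stop("gamma_brute_force is an oracle for planes up to 64 x 64")
  roi_m <- .apply_neighborhood_rule(pre$roi_m, evaluated, criteria, pre$spacing)
  k <- pre$k * as.integer(refine)
  E <- .upsample_plane(evaluated$values, evaluated$valid, k)
  stepf <- pre$spacing / k
  cu <- (seq_len(nrow(E)) - 1) * stepf     # fine-lattice coords, mm
  cv <- (seq_len(ncol(E)) - 1) * stepf
  idx <- which(roi_m, arr.ind = TRUE)
  dref <- reference$values[idx]
  gvals <- rep(NA_real_, nrow(idx))
  dta2 <- criteria$dta_mm^2
  for (p in seq_len(nrow(idx))) {
    pu <- (idx[p, 1] - 1) * pre$spacing
    pv <- (idx[p, 2] - 1) * pre$spacing
    sp2 <- outer((cu - pu)^2, (cv - pv)^2, "+") / dta2
    g2 <- sp2 + ((E - dref[p]) / pre$denom)^2
    gvals[p] <- sqrt(min(g2, na.rm = TRUE))
  }
  gmat <- matrix(NA_real_, nrow(roi_m), ncol(roi_m))
  gmat[idx] <- gvals
  pass <- matrix(FALSE, nrow(roi_m), ncol(roi_m))
  pass[idx] <- gvals <= 1 + PASS_TOL
  roi$mask <- roi_m
  gamma_result(gmat, pass, criteria, pre$dnorm, roi)
}

#' Summarize per-beam gamma pass rates
#'
#' @param results list of [gamma_result()] (one per beam).
#' @param threshold passing threshold, percent (95 by default).
#' @return an object of class `pass_rate_summary`: per-beam verdicts plus
#'   the plan mean, min, max and standard deviation of per-beam rates.
#' @export
pass_rate_summary <- function(results, threshold = 95) {
  stopifnot(length(results) >= 1,
            all(vapply(results, inherits, TRUE, "gamma_result")))
  rates <- vapply(results, `[[`, 0, "pass_rate")
  per_beam <- data.frame(
    beam = seq_along(results),
    pass_rate = rates,
    verdict = ifelse(rates >= threshold, "pass", "fail"),
    stringsAsFactors = FALSE)
  structure(list(per_beam = per_beam, threshold = threshold,
                 mean = mean(rates), min = min(rates), max = max(rates),
                 sd = if (length(rates) > 1) stats::sd(rates) else 0,
                 n_pass = sum(rates >= threshold), n = length(rates)),
            class = "pass_rate_summary")
}

#' @export
print.pass_rate_summary <- function(x, ...) {
  cat(sprintf("<pass_rate_summary> %d/%d beams pass at %.0f%%; mean %.1f%% (sd %.1f, range %.1f-%.1f)\n",
              x$n_pass, x$n, x$threshold, x$mean, x$sd, x$min, x$max))
  invisible(x)
}
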