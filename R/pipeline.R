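# End-to-end IMU pipeline: plan conversion check, per-beam plane extraction,
# shift and attenuation corrections, CIAO-masked gamma at each criteria set,
# point-dose cross-check, QA report and pass/fail contingency analysis.

# analysis-plane extent: CIAO bounding box (projected at the reference-point
# plane) plus a margin, centered on the reference point
.plane_extent_for_beam <- function(beam, spacing_mm, margin_mm) {
  half_u <- 0; half_v <- 0
  for (cp in beam$control_points) {
    open_ <- (cp$bank_b - cp$bank_a) > LEAF_CLOSED_TOL_CM
    if (!any(open_)) next
    half_v <- max(half_v, abs(cp$bank_a[open_]), abs(cp$bank_b[open_]))
    ob <- beam$geometry$leaf_boundaries[c(which(open_), which(open_) + 1L)]
    half_u <- max(half_u, abs(ob))
  }
  if (half_u == 0 || half_v == 0)
    stop("beam ", beam$beam_number, ": no open control point")
  proj <- beam$source_distance_cm / beam$sad   # definition plane -> isocenter
  n_of <- function(half_cm) {
    half_mm <- half_cm * 10 * proj + margin_mm
    2L * as.integer(ceiling(half_mm / spacing_mm)) + 1L
  }
  c(n_of(half_u), n_of(half_v))
}

#' Run the full IMU comparison for one plan
#'
#' Reads a Monaco-dialect RT Plan and per-beam dose files from two engines,
#' checks the plan converts cleanly to the Eclipse dialect (the doses are
#' precomputed, so conversion is a validation step), then per beam: extracts
#' the BEV-parallel plane through the plan reference point from both grids,
#' shifts the reference plane by the configured B-field correction, applies
#' the posterior-coil factor to the evaluated plane of posterior beams,
#' builds the CIAO ROI, and scores gamma at every configured criteria set.
#' The verdict uses the first (primary) criteria set at the configured
#' threshold. Deterministic given inputs.
#'
#' @param plan_path RT Plan file (Monaco dialect).
#' @param reference_dose_dir directory of per-beam RT Dose files from the
#'   primary (B-field-aware) engine.
#' @param evaluated_dose_dir directory of per-beam RT Dose files from the
#'   second engine.
#' @param config an [imu_config()].
#' @param verbose log per-stage progress to stderr.
#' @return an object of class `imu_report`: per-beam records (data frame),
#'   the [pass_rate_summary()] at the primary criteria, the gamma results,
#'   and the configuration echo.
#' @export
run_imu <- function(plan_path, reference_dose_dir, evaluated_dose_dir,
                    config = imu_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[3]
  plan <- read_rtplan(plan_path)
  converted <- convert_plan(plan, config$conversion)
  v <- validate_plan(converted)
  if (nrow(v) > 0)
    stop("converted plan does not validate: ", v$message[1])
  say("plan %s: %d beams read and converted [%.1fs]", plan$fraction_label,
      length(plan$beams), proc.time()[3] - t0)
  read_dir <- function(d) {
    files <- list.files(d, pattern = "\\.dcm$", full.names = TRUE)
    grids <- lapply(files, read_rtdose)
    names(grids) <- vapply(grids, function(g) as.character(g$beam_number), "")
    grids
  }
  ref_grids <- read_dir(reference_dose_dir)
  eval_grids <- read_dir(evaluated_dose_dir)
  beam_numbers <- vapply(plan$beams, `[[`, 0L, "beam_number")
  orphans <- c(
    setdiff(as.character(beam_numbers), names(ref_grids)),
    setdiff(as.character(beam_numbers), names(eval_grids)),
    setdiff(names(ref_grids), as.character(beam_numbers)),
    setdiff(names(eval_grids), as.character(beam_numbers)))
  if (length(orphans) > 0)
    stop("beam/dose pairing mismatch; orphan beam numbers: ",
         paste(unique(orphans), collapse = ", "))
  pr <- run_imu_on_grids(plan, ref_grids[as.character(beam_numbers)],
                         eval_grids[as.character(beam_numbers)], config,
                         verbose = verbose)
  pr$plan_path <- plan_path
  pr
}

#' Run the IMU comparison on in-memory grids
#'
#' The computational core of [run_imu()], also usable directly on an
#' `imu_case` built by [make_synthetic_case()].
#'
#' @param plan a [plan_record()] (Monaco dialect).
#' @param ref_grids,eval_grids per-beam [dose_grid()] lists, in beam order.
#' @param config an [imu_config()].
#' @param verbose log per-beam progress to stderr.
#' @return an `imu_report` (see [run_imu()]).
#' @export
run_imu_on_grids <- function(plan, ref_grids, eval_grids,
                             config = imu_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  cr_list <- config$gamma$criteria
  cr_names <- vapply(cr_list, format, "")
  corr <- config$corrections
  shift_mm <- corr$shift_sign * corr$bfield_shift_mm
  rows <- list(); gammas <- list()
  for (bi in seq_along(plan$beams)) {
    t0 <- proc.time()[3]
    beam <- plan$beams[[bi]]
    extent <- .plane_extent_for_beam(beam, config$plane$spacing_mm,
                                     config$plane$margin_mm)
    spec <- bev_plane_for_beam(beam, plan$reference_point,
                               spacing = config$plane$spacing_mm,
                               extent = extent)
    ref_plane <- sample_plane(ref_grids[[bi]], spec, role = "reference")
    ref_plane <- shift_plane(ref_plane, shift_mm)
    eval_plane <- sample_plane(eval_grids[[bi]], spec, role = "evaluated")
    posterior <- classify_posterior(beam, corr)
    factor <- if (posterior) corr$posterior_coil_factor
              else corr$anterior_coil_factor
    if (factor != 1) eval_plane <- apply_attenuation(eval_plane, factor)
    roi <- ciao_mask(beam, spec)
    roi$mask <- roi$mask & ref_plane$valid & eval_plane$valid
    g <- lapply(cr_list, function(cr)
      gamma_map(ref_plane, eval_plane, roi, cr))
    rates <- vapply(g, `[[`, 0, "pass_rate")
    pd <- point_dose_compare(ref_grids[[bi]], eval_grids[[bi]],
                             plan$reference_point, correction_factor = factor)
    row <- data.frame(beam = beam$beam_number, gantry = beam$gantry_angle,
                      posterior = posterior, coil_factor = factor,
                      shift_mm = shift_mm,
                      point_diff_pct = pd,
                      stringsAsFactors = FALSE)
    for (k in seq_along(rates)) row[[paste0("pass_", cr_names[k])]] <- rates[k]
    row$verdict <- ifelse(rates[1] >= config$gamma$threshold_pct,
                          "pass", "fail")
    rows[[bi]] <- row
    gammas[[bi]] <- g
    say("beam %d (gantry %.0f): %s [%.1fs]", beam$beam_number,
        beam$gantry_angle,
        paste(sprintf("%s=%.1f%%", cr_names, rates), collapse = " "),
        proc.time()[3] - t0)
  }
  records <- do.call(rbind, rows)
  summary_ <- pass_rate_summary(lapply(gammas, `[[`, 1),
                                threshold = config$gamma$threshold_pct)
  structure(list(records = records, summary = summary_, gammas = gammas,
                 config = config, fraction_label = plan$fraction_label,
                 machine_label = plan$machine_label, plan_path = NULL),
            class = "imu_report")
}

#' @export
print.imu_report <- function(x, ...) {
  cat(sprintf("<imu_report> %s: %d beams, plan verdict %s\n",
              x$fraction_label, nrow(x$records),
              if (all(x$records$verdict == "pass")) "PASS" else "FAIL"))
  print(x$summary)
  invisible(x)
}

#' Point dose comparison between two grids
#'
#' Coarse cross-check: the raw grid values at one point (trilinear), the
#' evaluated value multiplied by the same posterior/anterior correction
#' factor used in the gamma step, reported as a percent difference. No
#' lateral shift is involved (the point check compares stored doses).
#'
#' @param reference,evaluated [dose_grid()] objects.
#' @param point 3-vector, mm.
#' @param correction_factor factor applied to the evaluated value.
#' @return percent difference `100 * (eval * f - ref) / ref`.
#' @export
point_dose_compare <- function(reference, evaluated, point,
                               correction_factor = 1.0) {
  d_ref <- interp_grid(reference, matrix(point, 1))
  d_eval <- interp_grid(evaluated, matrix(point, 1))
  if (is.na(d_ref) || is.na(d_eval))
    stop("point lies outside a dose grid")
  if (d_ref == 0) stop("zero reference dose at the comparison point")
  100 * (d_eval * correction_factor - d_ref) / d_ref
}

#' Contingency analysis of two pass/fail verdict sets
#'
#' Cross-tabulates the verdicts of two QA modalities on the same beams,
#' computes the Pearson contingency coefficient `sqrt(chi2 / (chi2 + n))`
#' (uncorrected chi-squared) and an exact (Fisher) p-value. A degenerate
#' table (a modality with only one outcome) yields coefficient 0 with a
#' warning. For a 2x2 table the coefficient is bounded by `sqrt(1/2)`.
#'
#' @param verdicts_a,verdicts_b logical vectors (TRUE = pass), equal length
#'   `>= 2`.
#' @return an object of class `contingency_result`: `table`, `coefficient`,
#'   `p_value`, `n`.
#' @export
contingency_analysis <- function(verdicts_a, verdicts_b) {
  stopifnot(is.logical(verdicts_a), is.logical(verdicts_b),
            length(verdicts_a) == length(verdicts_b),
            length(verdicts_a) >= 2)
  a <- factor(ifelse(verdicts_a, "pass", "fail"), levels = c("pass", "fail"))
  b <- factor(ifelse(verdicts_b, "pass", "fail"), levels = c("pass", "fail"))
  tab <- table(A = a, B = b)
  n <- sum(tab)
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) {
    warning("degenerate contingency table (one modality has a single outcome)")
    chi2 <- 0
    p <- 1
  } else {
    expected <- outer(rs, cs) / n
    chi2 <- sum((tab - expected)^2 / expected)
    p <- stats::fisher.test(tab)$p.value
  }
  structure(list(table = tab, coefficient = sqrt(chi2 / (chi2 + n)),
                 p_value = p, n = n),
            class = "contingency_result")
}

#' @export
print.contingency_result <- function(x, ...) {
  cat(sprintf("<contingency_result> n=%d, coefficient %.3f, exact p=%.3g\n",
              x$n, x$coefficient, x$p_value))
  print(x$table)
  invisible(x)
}

#' Render a QA report to a text file
#'
#' Human-readable per-beam table, plan verdict and a configuration echo
#' (criteria, shift, corrections) for auditability. Regenerating from the
#' same records yields identical content (no timestamps).
#'
#' @param report an `imu_report` from [run_imu()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
render_report <- function(report, path) {
  stopifnot(inherits(report, "imu_report"))
  r <- report$records
  cr_cols <- grep("^pass_", names(r), value = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("independent monitor-unit second check -- per-beam gamma report")
  w("plan: %s   machine: %s", report$fraction_label, report$machine_label)
  w("criteria: %s (primary first); threshold %.0f%%; reference shift %+.1f mm along BEV-Y",
    paste(vapply(report$config$gamma$criteria, format, ""), collapse = ", "),
    report$config$gamma$threshold_pct, r$shift_mm[1])
  w("posterior coil factor %.3f for gantry in [%.0f, %.0f] deg",
    report$config$corrections$posterior_coil_factor,
    report$config$corrections$posterior_gantry_range[1],
    report$config$corrections$posterior_gantry_range[2])
  w("")
  hdr <- sprintf("%5s %7s %5s %7s %s %9s %8s", "beam", "gantry", "post.",
                 "coil", paste(sprintf("%12s", cr_cols), collapse = " "),
                 "ptdiff%", "verdict")
  w("%s", hdr)
  for (i in seq_len(nrow(r))) {
    flag <- if (r$verdict[i] == "fail") "  <-- FAIL" else ""
    w("%5d %7.1f %5s %7.3f %s %9.2f %8s%s",
      r$beam[i], r$gantry[i], ifelse(r$posterior[i], "yes", "no"),
      r$coil_factor[i],
      paste(sprintf("%11.1f%%", unlist(r[i, cr_cols])), collapse = " "),
      r$point_diff_pct[i], r$verdict[i], flag)
  }
  w("")
  s <- report$summary
  w("plan summary: %d/%d beams pass at %.0f%%; mean %.1f%% (sd %.1f, min %.1f, max %.1f)",
    s$n_pass, s$n, s$threshold, s$mean, s$sd, s$min, s$max)
  w("plan verdict: %s", if (s$n_pass == s$n) "PASS" else "FAIL")
  invisible(path)
}
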