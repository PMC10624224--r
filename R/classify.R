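#' Assemble per-case metrics for classification
#'
#' Collects the quantities the decision procedure consumes: the epidermis/
#' dermis boundary depth `Z`, the maximum pigmentation depth `D` of the
#' lesional skin, and the mean vessel diameter and density of lesional
#' (`_ls`) and non-lesional (`_ns`) skin, plus optional correlation
#' statistics and per-tile replicate lists for significance testing.
#'
#' @param Z,D depths below the skin surface, micrometres.
#' @param Phi_ls,Phi_ns mean vessel diameters, micrometres.
#' @param rho_ls,rho_ns vessel densities, fractions in `[0, 1]`.
#' @param r_ls,p_corr_ls lesional diameter-density correlation and p-value.
#' @param diam_reps_ls,diam_reps_ns,dens_reps_ls,dens_reps_ns per-tile
#'   replicate vectors used by [compare_groups()].
#' @param case_id identifier.
#' @return An object of class `case_metrics`.
#' @export
case_metrics <- function(Z, D, Phi_ls, Phi_ns, rho_ls, rho_ns,
                         r_ls = NA_real_, p_corr_ls = NA_real_,
                         diam_reps_ls = numeric(), diam_reps_ns = numeric(),
                         dens_reps_ls = numeric(), dens_reps_ns = numeric(),
                         case_id = "case") {
  m <- list(case_id = case_id, Z = Z, D = D,
            Phi_ls = Phi_ls, Phi_ns = Phi_ns,
            rho_ls = rho_ls, rho_ns = rho_ns,
            r_ls = r_ls, p_corr_ls = p_corr_ls,
            diam_reps_ls = diam_reps_ls, diam_reps_ns = diam_reps_ns,
            dens_reps_ls = dens_reps_ls, dens_reps_ns = dens_reps_ns)
  for (f in c("Z", "D", "Phi_ls", "Phi_ns", "rho_ls", "rho_ns")) {
    v <- m[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("case_metrics field `", f, "` must be a single finite number")
    if (v < 0) stop("case_metrics field `", f, "` must be non-negative")
  }
  for (f in c("rho_ls", "rho_ns"))
    if (m[[f]] > 1) stop("`", f, "` is a fraction in [0, 1], got ", m[[f]])
  structure(m, class = "case_metrics")
}

#' Four-way melasma classification from lesional/control metrics
#'
#' Applies the two-stage decision procedure. Layer call: pigment confined
#' to the epidermis (`D <= Z`) is epidermal, pigment reaching the dermis
#' (`D > Z`) is mixed. Vascular call: the case is M+V only when both the
#' mean vessel diameter and the mean vessel density of the lesional skin
#' strictly exceed those of the non-lesional skin; ties and single
#' exceedances fall to M. The composed label is one of Epidermal M,
#' Epidermal M+V, Mixed M, Mixed M+V.
#'
#' Significance of the vessel differences (from [compare_groups()] on the
#' replicate lists) is reported alongside but does not gate the call unless
#' `require_significance = TRUE`, in which case both vessel comparisons must
#' also reach `alpha`.
#'
#' @param metrics a [case_metrics()].
#' @param require_significance also require `p < alpha` on both vessel
#'   comparisons for M+V.
#' @param alpha significance level used when gating.
#' @param method group test passed to [compare_groups()].
#' @param flags character vector of upstream warnings (e.g. low-confidence
#'   boundary) carried into the result.
#' @return An object of class `classification_result`: list with
#'   `layer_call`, `vascular_call`, `label`, `supporting` (the metrics),
#'   `p_diameter`, `p_density` (when replicates are available) and `flags`.
#' @export
classify_case <- function(metrics, require_significance = FALSE, alpha = 0.05,
                          method = c("welch", "wilcoxon"),
                          flags = character()) {
  if (!inherits(metrics, "case_metrics"))
    stop("`metrics` must be a case_metrics object")
  method <- match.arg(method)
  layer_call <- if (metrics$D <= metrics$Z) "epidermal" else "mixed"
  vessels_greater <- metrics$Phi_ls > metrics$Phi_ns &&
    metrics$rho_ls > metrics$rho_ns
  p_diam <- p_dens <- NA_real_
  if (length(metrics$diam_reps_ls) >= 2L && length(metrics$diam_reps_ns) >= 2L)
    p_diam <- compare_groups(metrics$diam_reps_ls, metrics$diam_reps_ns,
                             method = method)$p
  if (length(metrics$dens_reps_ls) >= 2L && length(metrics$dens_reps_ns) >= 2L)
    p_dens <- compare_groups(metrics$dens_reps_ls, metrics$dens_reps_ns,
                             method = method)$p
  if (require_significance) {
    if (is.na(p_diam) || is.na(p_dens))
      stop("require_significance = TRUE needs replicate lists in the metrics")
    vessels_greater <- vessels_greater && p_diam < alpha && p_dens < alpha
  }
  vascular_call <- if (vessels_greater) "M+V" else "M"
  label <- paste(if (layer_call == "epidermal") "Epidermal" else "Mixed",
                 vascular_call)
  structure(list(layer_call = layer_call, vascular_call = vascular_call,
                 label = label, supporting = metrics,
                 p_diameter = p_diam, p_density = p_dens,
                 flags = flags),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  m <- x$supporting
  cat(sprintf("<classification> %s: %s\n", m$case_id, x$label))
  cat(sprintf("  Z = %g um, D = %g um -> %s\n", m$Z, m$D, x$layer_call))
  cat(sprintf("  Phi %g vs %g um, rho %.1f%% vs %.1f%% -> %s\n",
              m$Phi_ls, m$Phi_ns, 100 * m$rho_ls, 100 * m$rho_ns,
              x$vascular_call))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' Compare lesional and non-lesional replicate measurements
#'
#' Two-sided Welch t-test by default (Mann-Whitney optionally), returning
#' the p-value and the direction of the lesional minus non-lesional mean
#' difference. Identical groups (zero variance, zero difference) return
#' `p = 1`; distinct constant groups return `p = 0`.
#'
#' @param replicates_ls,replicates_ns numeric vectors, length >= 2 each.
#' @param method `"welch"` or `"wilcoxon"`.
#' @return A list with `p`, `direction` (sign of the mean difference) and
#'   `method`.
#' @export
compare_groups <- function(replicates_ls, replicates_ns,
                           method = c("welch", "wilcoxon")) {
  method <- match.arg(method)
  if (length(replicates_ls) < 2L || length(replicates_ns) < 2L)
    stop("each group needs at least 2 replicates")
  delta <- mean(replicates_ls) - mean(replicates_ns)
  p <- tryCatch({
    if (method == "welch")
      stats::t.test(replicates_ls, replicates_ns, var.equal = FALSE)$p.value
    else
      stats::wilcox.test(replicates_ls, replicates_ns, exact = FALSE)$p.value
  }, error = function(e) {
    # degenerate zero-variance data: identical groups are maximally
    # compatible with the null, distinct constants maximally incompatible
    if (delta == 0) 1 else 0
  })
  list(p = p, direction = sign(delta), method = method)
}

#' Mean of a per-case metric over a patient group
#'
#' @param values numeric vector of per-case values (non-empty).
#' @return Arithmetic mean.
#' @export
group_mean_metric <- function(values) {
  if (length(values) == 0L) stop("empty value list")
  mean(values)
}
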