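# Temperature-sensitivity analysis of ebullitive CH4 flux: 1-degree binning,
# polynomial and Arrhenius fits on binned means, and pairwise
# homogeneity-of-slopes (interaction) tests with robustness subsets.

GAS_R <- 8.314  # J mol-1 K-1

#' Bin flux records into temperature intervals
#'
#' Bins are half-open, integer-anchored intervals `[k, k+1)` degrees C (for
#' `width_C = 1`), with centers at `k + width/2`. Within each lake-zone
#' group and bin, the mean flux and a Student-t 95% confidence interval on
#' the within-bin flux values are computed. Empty bins are omitted;
#' single-record bins are kept but flagged `degenerate` (their CI is NA).
#'
#' @param records data frame of flux records (`lake`, `zone`, `temp_C`,
#'   `flux_mg_m2_d`) as produced by [generate_flux_records()] or read with
#'   [read_flux_csv()].
#' @param width_C bin width in degrees C (> 0).
#' @param conf confidence level for the t interval.
#' @return data frame with `lake`, `zone`, `bin_center_C`, `n`, `mean_flux`,
#'   `ci_lo`, `ci_hi`, `degenerate`.
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' bins <- bin_flux(generate_flux_records(cfg))
#' head(bins)
bin_flux <- function(records, width_C = 1, conf = 0.95) {
  if (width_C <= 0) stop("bin width must be positive")
  if (nrow(records) == 0) stop("no flux records supplied")
  k <- floor(records$temp_C / width_C)
  key <- interaction(records$lake, records$zone, k, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(records)), key), function(idx) {
    x <- records$flux_mg_m2_d[idx]
    n <- length(x)
    m <- mean(x)
    if (n > 1) {
      half <- qt(1 - (1 - conf) / 2, n - 1) * sd(x) / sqrt(n)
      ci <- m + c(-1, 1) * half
    } else {
      ci <- c(NA_real_, NA_real_)
    }
    data.frame(lake = records$lake[idx[1]], zone = records$zone[idx[1]],
               bin_center_C = (k[idx[1]] + 0.5) * width_C,
               n = n, mean_flux = m, ci_lo = ci[1], ci_hi = ci[2],
               degenerate = n == 1)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$lake, out$zone, out$bin_center_C), ]
}

#' Polynomial fit of binned mean flux on temperature
#'
#' Ordinary (unweighted) least squares of mean bin flux on powers of the bin
#' center temperature, per lake-zone group.
#'
#' @param bins output of [bin_flux()].
#' @param degree polynomial degree (default 2).
#' @return data frame with one row per group: coefficients `c0..cdegree`
#'   (ascending powers) and `r2`.
#' @export
fit_polynomial <- function(bins, degree = 2) {
  groups <- split(bins, interaction(bins$lake, bins$zone, drop = TRUE))
  rows <- lapply(groups, function(b) {
    if (nrow(b) < degree + 1) {
      stop("fewer bins (", nrow(b), ") than polynomial coefficients (",
           degree + 1, ") for group ", b$lake[1], " ", b$zone[1])
    }
    fit <- lm(mean_flux ~ poly(bin_center_C, degree, raw = TRUE), data = b)
    cf <- setNames(coef(fit), paste0("c", 0:degree))
    r2 <- if (nrow(b) == degree + 1) 1 else summary(fit)$r.squared
    cbind(data.frame(lake = b$lake[1], zone = b$zone[1]),
          as.data.frame(as.list(cf)), data.frame(r2 = r2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Arrhenius regression on binned flux
#'
#' Fits `ln(mean_flux) ~ 1/T_K` (with `T_K = bin_center_C + 273.15`) per
#' lake-zone group by ordinary least squares on the binned means. Bins with
#' non-positive mean flux are dropped with a warning. The apparent
#' activation energy is `-slope * R` (R = 8.314 J mol-1 K-1), reported in
#' kJ mol-1.
#'
#' @param bins output of [bin_flux()].
#' @param weights `"none"` (default; the fit is to binned means) or `"n"` to
#'   weight each bin by its record count.
#' @return data frame of class `arrhenius_fits`: one row per group with
#'   `slope_K`, `se_slope`, `intercept`, `r2`, `apparent_Ea_kJ_mol`,
#'   `n_bins`.
#' @export
fit_arrhenius <- function(bins, weights = c("none", "n")) {
  weights <- match.arg(weights)
  groups <- split(bins, interaction(bins$lake, bins$zone, drop = TRUE))
  rows <- lapply(groups, function(b) {
    bad <- b$mean_flux <= 0
    if (any(bad)) {
      warning(sum(bad), " bin(s) with non-positive mean flux dropped for ",
              b$lake[1], " ", b$zone[1])
      b <- b[!bad, , drop = FALSE]
    }
    if (nrow(b) < 3) {
      stop("fewer than 3 usable bins for group ", b$lake[1], " ", b$zone[1])
    }
    inv_t <- 1 / (b$bin_center_C + 273.15)
    w <- if (weights == "n") b$n else NULL
    fit <- lm(log(b$mean_flux) ~ inv_t, weights = w)
    sm <- summary(fit)
    data.frame(lake = b$lake[1], zone = b$zone[1],
               slope_K = unname(coef(fit)[2]),
               se_slope = sm$coefficients[2, 2],
               intercept = unname(coef(fit)[1]),
               r2 = sm$r.squared,
               apparent_Ea_kJ_mol = -unname(coef(fit)[2]) * GAS_R / 1000,
               n_bins = nrow(b))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("arrhenius_fits", "data.frame")
  out
}

apply_subset <- function(b, subset) {
  has_both <- all(c("edge", "middle") %in% b$zone)
  if (subset == "full" || !has_both) return(b)
  mid <- b$zone == "middle"
  if (subset == "edge_trimmed") {
    keep <- mid | b$bin_center_C <= max(b$bin_center_C[mid])
    return(b[keep, , drop = FALSE])
  }
  drop_c <- if (subset == "drop_top_middle_bin") {
    max(b$bin_center_C[mid])
  } else {
    min(b$bin_center_C[mid])
  }
  b[!(mid & b$bin_center_C == drop_c), , drop = FALSE]
}

#' Pairwise homogeneity-of-slopes tests on Arrhenius plots
#'
#' For every pair of lake-zone groups, fits the pooled interaction model
#' `ln(flux) ~ group + invT + group:invT` on the binned means (or raw
#' records, see `x`) and reports the F-test p-value of the interaction term:
#' a significant interaction means the two groups' temperature sensitivities
#' (Arrhenius slopes) differ. Three robustness subsets are supported for
#' edge-versus-middle pairs: `edge_trimmed` removes edge bins above the
#' warmest middle bin, `drop_top_middle_bin` and `drop_bottom_middle_bin`
#' remove the warmest or coldest middle bin.
#'
#' @param x binned means from [bin_flux()] (default analysis mode), or raw
#'   flux records (a data frame with a `flux_mg_m2_d` column), in which case
#'   the interaction model is fit to individual log fluxes.
#' @param subset one of `"full"`, `"edge_trimmed"`, `"drop_top_middle_bin"`,
#'   `"drop_bottom_middle_bin"`.
#' @param alpha significance level for the `significant` flag.
#' @return data frame with one row per pair: `group_a`, `group_b`,
#'   `subset`, `interaction_p`, `significant`, `skipped`.
#' @export
compare_slopes <- function(x,
                           subset = c("full", "edge_trimmed",
                                      "drop_top_middle_bin",
                                      "drop_bottom_middle_bin"),
                           alpha = 0.05) {
  subset <- match.arg(subset)
  raw <- "flux_mg_m2_d" %in% names(x)
  if (raw) {
    x <- x[x$flux_mg_m2_d > 0, , drop = FALSE]
    x$bin_center_C <- x$temp_C
    x$mean_flux <- x$flux_mg_m2_d
  }
  x$group <- paste(x$lake, x$zone, sep = "-")
  grp <- unique(x$group)
  if (length(grp) < 2) stop("need at least two groups to compare")
  pairs <- combn(sort(grp), 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    g <- pairs[, j]
    b <- apply_subset(x[x$group %in% g, , drop = FALSE], subset)
    counts <- table(b$group)
    if (length(counts) < 2 || any(counts < 3)) {
      warning("comparison ", g[1], " vs ", g[2], " skipped: a group has ",
              "fewer than 3 points after subsetting")
      return(data.frame(group_a = g[1], group_b = g[2], subset = subset,
                        interaction_p = NA_real_, significant = NA,
                        skipped = TRUE))
    }
    b$inv_t <- 1 / (b$bin_center_C + 273.15)
    b$lnF <- log(b$mean_flux)
    full <- lm(lnF ~ group * inv_t, data = b)
    reduced <- lm(lnF ~ group + inv_t, data = b)
    p <- anova(reduced, full)[2, "Pr(>F)"]
    data.frame(group_a = g[1], group_b = g[2], subset = subset,
               interaction_p = p, significant = p < alpha, skipped = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' CH4 production rate from an incubation headspace time series
#'
#' Rate is the OLS slope of headspace CH4 amount against time, normalized by
#' sediment dry mass. Negative slopes are returned as-is with a flag.
#'
#' @param times_d sampling times in days (at least 2, strictly increasing).
#' @param headspace_CH4 headspace CH4 amount at each time (any amount unit).
#' @param dry_mass_g sediment dry mass in g (> 0).
#' @return list with `rate` (amount per g dry sediment per day), `slope`,
#'   `r2`, and `negative` flag.
#' @export
#' @examples
#' incubation_rate(0:5, c(0, 1, 2, 3, 4, 5), dry_mass_g = 2)$rate  # 0.5
incubation_rate <- function(times_d, headspace_CH4, dry_mass_g) {
  if (dry_mass_g <= 0) stop("dry mass must be positive")
  if (length(times_d) < 2 || any(diff(times_d) <= 0)) {
    stop("need at least two strictly increasing timepoints")
  }
  if (length(headspace_CH4) != length(times_d)) {
    stop("times and headspace series differ in length")
  }
  fit <- lm(headspace_CH4 ~ times_d)
  slope <- unname(coef(fit)[2])
  r2 <- if (var(headspace_CH4) == 0) NA_real_ else summary(fit)$r.squared
  list(rate = slope / dry_mass_g, slope = slope, r2 = r2,
       negative = slope < 0)
}
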