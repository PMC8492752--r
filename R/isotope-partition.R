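# Depth-resolved fugitive-CH4 mass balance from stable carbon isotopes.
#
# Model: fermentation/respiration generate DIC without fractionating carbon
# (DIC endmember at d13C of the organic substrate), while methanogenesis
# generates CH4 and CO2 1:1 and fractionates. The CH4 isotope ratio fixes
# the fractionation factor; 1:1 mass balance on the substrate fixes the
# methanogenic CO2 endmember; the measured DIC isotope ratio then gives the
# fraction f of DIC derived from methanogenesis. f times the measured DIC
# concentration is the CH4 generated at that depth (steady state); whatever
# exceeds the measured porewater CH4 escaped as "fugitive" CH4.

#' Isotope fractionation factor of methanogenesis
#'
#' `alpha = (d13C_substrate + 1000) / (d13C_CH4 + 1000)`, assuming the
#' substrate's isotopic composition matches the measured bulk organic
#' carbon.
#'
#' @param d13C_substrate substrate d13C (permil VPDB).
#' @param d13C_CH4 methane d13C (permil VPDB).
#' @return fractionation factor (dimensionless, > 0). Vectorized.
#' @export
#' @examples
#' fractionation_factor(-28, -80)  # 972/920 = 1.0565
fractionation_factor <- function(d13C_substrate, d13C_CH4) {
  if (any(d13C_CH4 == -1000)) stop("d13C_CH4 of -1000 permil is singular")
  alpha <- (d13C_substrate + 1000) / (d13C_CH4 + 1000)
  if (any(alpha <= 0)) stop("non-physical isotope inputs: alpha <= 0")
  alpha
}

#' Apparent fractionation between DIC and CH4, with pathway call
#'
#' `alphaC = (d13C_DIC + 1000) / (d13C_CH4 + 1000)`. Large apparent
#' fractionation is diagnostic of hydrogenotrophic (CO2/H2) methanogenesis,
#' small of acetoclastic; the default thresholds (1.065 / 1.055) follow the
#' classical isotope-zonation convention and are configurable.
#'
#' @param d13C_DIC,d13C_CH4 measured d13C (permil VPDB). Vectorized.
#' @param thresholds numeric `c(acetoclastic, hydrogenotrophic)`: alphaC at
#'   or below the first is called acetoclastic, at or above the second
#'   hydrogenotrophic, otherwise intermediate.
#' @return data frame with `alphaC` and `pathway`.
#' @export
#' @examples
#' apparent_alpha_c(-2, -80)  # 1.0848, hydrogenotrophic
apparent_alpha_c <- function(d13C_DIC, d13C_CH4,
                             thresholds = c(acetoclastic = 1.055,
                                            hydrogenotrophic = 1.065)) {
  stopifnot(length(thresholds) == 2, thresholds[1] <= thresholds[2])
  alphaC <- (d13C_DIC + 1000) / (d13C_CH4 + 1000)
  pathway <- ifelse(alphaC >= thresholds[2], "hydrogenotrophic",
                    ifelse(alphaC <= thresholds[1], "acetoclastic",
                           "intermediate"))
  data.frame(alphaC = alphaC, pathway = pathway)
}

# The two-endmember mixing geometry, isolated so an alternative closure
# (e.g. a Rayleigh variant) can be substituted in one place.
dic_endmembers <- function(d13C_TOC, d13C_CH4) {
  list(nonfractionating = d13C_TOC,
       methanogenic = 2 * d13C_TOC - d13C_CH4)
}

#' Depth-resolved fugitive CH4 from the isotope mass balance
#'
#' For each core-depth row: the methanogenic CO2 endmember is
#' `2 * d13C_TOC - d13C_CH4` (1:1 CH4:CO2 on the substrate); the fraction
#' of DIC derived from methanogenesis is
#' `f = (d13C_DIC - d13C_TOC) / (d13C_CO2meth - d13C_TOC)`, clipped to
#' `[0, 1]` with a flag (field noise can push it slightly out); generated
#' CH4 is `f * DIC_uM`; fugitive CH4 is generated minus measured porewater
#' CH4 and may be negative (flagged, not clipped - a steady-state
#' violation is diagnostic information). Rows where `d13C_CH4 == d13C_TOC`
#' (degenerate endmembers) return NA with the `undefined` flag.
#'
#' @param s data frame of core geochemistry with columns `depth_cm`,
#'   `d13C_TOC`, `d13C_CH4`, `d13C_DIC`, `CH4_uM`, `DIC_uM` (extra columns
#'   such as `sample`, `core`, `zone` are carried through).
#' @param thresholds pathway thresholds passed to [apparent_alpha_c()].
#' @return data frame with one row per input row: `alpha`, `alphaC`,
#'   `pathway`, `f_meth` (clipped), `f_meth_raw`, `generated_CH4_uM`,
#'   `fugitive_CH4_uM`, and logical flags `f_clipped`, `negative_fugitive`,
#'   `undefined`.
#' @export
#' @examples
#' s <- data.frame(depth_cm = 10, d13C_TOC = -28, d13C_CH4 = -80,
#'                 d13C_DIC = -2, CH4_uM = 300, DIC_uM = 2000)
#' fugitive_ch4(s)  # f = 0.5, generated 1000 uM, fugitive 700 uM
fugitive_ch4 <- function(s, thresholds = c(acetoclastic = 1.055,
                                           hydrogenotrophic = 1.065)) {
  need <- c("depth_cm", "d13C_TOC", "d13C_CH4", "d13C_DIC",
            "CH4_uM", "DIC_uM")
  miss <- setdiff(need, names(s))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  em <- dic_endmembers(s$d13C_TOC, s$d13C_CH4)
  denom <- em$methanogenic - em$nonfractionating
  undefined <- denom == 0
  f_raw <- ifelse(undefined, NA_real_,
                  (s$d13C_DIC - em$nonfractionating) / denom)
  f <- pmin(pmax(f_raw, 0), 1)
  generated <- f * s$DIC_uM
  fugitive <- generated - s$CH4_uM
  ac <- apparent_alpha_c(s$d13C_DIC, s$d13C_CH4, thresholds)
  keep <- intersect(c("sample", "core", "lake", "zone"), names(s))
  out <- cbind(
    s[keep],
    data.frame(
      depth_cm = s$depth_cm,
      alpha = fractionation_factor(s$d13C_TOC, s$d13C_CH4),
      alphaC = ac$alphaC,
      pathway = ac$pathway,
      f_meth = f, f_meth_raw = f_raw,
      generated_CH4_uM = generated,
      fugitive_CH4_uM = fugitive,
      f_clipped = !undefined & (f_raw < 0 | f_raw > 1),
      negative_fugitive = !undefined & fugitive < 0,
      undefined = undefined
    )
  )
  rownames(out) <- NULL
  out
}

#' Convert a headspace CH4 mixing ratio to a porewater concentration
#'
#' Ideal-gas conversion of a measured headspace mixing ratio to micromolar
#' CH4 in the sample's water. The NaOH-trap extraction used for total
#' sediment CH4 drives all CH4 into the headspace, so the headspace amount
#' over the water mass is the total concentration.
#'
#' @param ppm CH4 mixing ratio in the headspace (ppmv).
#' @param headspace_mL headspace volume (mL).
#' @param temp_C headspace temperature (deg C).
#' @param pressure_kPa headspace pressure (kPa).
#' @param water_mass_g mass of water in the sample (g, density 1 g/mL).
#' @return concentration in uM. Vectorized over `ppm`.
#' @export
#' @examples
#' headspace_to_concentration(10000, 23, 25, 101.325, 1.5)  # ~6267 uM
headspace_to_concentration <- function(ppm, headspace_mL, temp_C,
                                       pressure_kPa, water_mass_g) {
  if (any(ppm < 0)) stop("mixing ratio cannot be negative")
  if (headspace_mL <= 0 || water_mass_g <= 0 || pressure_kPa <= 0) {
    stop("volumes, mass and pressure must be positive")
  }
  moles <- ppm * 1e-6 * (pressure_kPa * 1000) * (headspace_mL * 1e-6) /
    (GAS_R * (temp_C + 273.15))
  moles / (water_mass_g / 1000) * 1e6  # mol/L -> uM
}

#' Correlate fugitive CH4 with community composition and lineages
#'
#' Mantel test (Spearman) between the Bray-Curtis dissimilarity of the
#' community and the Euclidean distance of per-sample fugitive CH4, plus
#' per-lineage OLS regressions of relative abundance on fugitive CH4.
#'
#' @param fugitive data frame with `sample` and `fugitive_CH4_uM` (e.g. from
#'   [fugitive_ch4()] run on chemistry carrying sample ids).
#' @param otu a `limnoch4_otu` table; samples are matched by id.
#' @param level taxonomy level for the lineage regressions (see
#'   [lineage_sums()]).
#' @param n_perm,seed Mantel permutations and seed.
#' @return list with `mantel` (rho, p, flags) and `lineages` (per-lineage
#'   slope, r2, p, ordered by p).
#' @export
correlate_fugitive_with_microbes <- function(fugitive, otu, level = 2,
                                             n_perm = 999, seed = 1) {
  common <- intersect(fugitive$sample, rownames(otu$counts))
  if (length(common) < 4) stop("fewer than 4 matched samples")
  fug <- fugitive$fugitive_CH4_uM[match(common, fugitive$sample)]
  counts <- otu$counts[common, , drop = FALSE]
  if (var(fug) == 0) {
    return(list(mantel = list(rho = NA_real_, p = NA_real_,
                              zero_variance = TRUE),
                lineages = NULL))
  }
  dm_comm <- bray_curtis(counts)
  dm_fug <- stats::dist(fug)
  mt <- mantel_test(dm_comm, dm_fug, n_perm = n_perm, seed = seed)
  rel <- lineage_sums(counts, otu$taxonomy, level = level)
  rows <- lapply(colnames(rel), function(ln) {
    if (var(rel[, ln]) == 0) return(NULL)
    fit <- summary(lm(rel[, ln] ~ fug))
    data.frame(lineage = ln, slope = fit$coefficients[2, 1],
               r2 = fit$r.squared, p = fit$coefficients[2, 4])
  })
  lineages <- do.call(rbind, rows)
  lineages <- lineages[order(lineages$p), ]
  rownames(lineages) <- NULL
  list(mantel = c(mt, list(zero_variance = FALSE)), lineages = lineages)
}
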