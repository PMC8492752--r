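#' Configuration for the synthetic two-lake sediment study
#'
#' Builds the single configuration object consumed by all synthetic-data
#' generators. Defaults emulate a two-lake (MH, IH), two-zone (edge, middle)
#' design: bubble-trap flux records whose log-flux follows a zone-specific
#' Arrhenius law with lognormal noise, four sediment cores (one per
#' lake-zone) sampled every 4 cm to 40 cm, porewater chemistry produced by a
#' forward stable-isotope mass balance, a zone- and depth-structured OTU
#' table with tagged functional guilds, and a qPCR plate with a log-linear
#' standard series.
#'
#' The middle-zone Arrhenius slope is 3.5-fold steeper than the edge slope by
#' default, middles carry roughly 3-fold higher methanogen and Syntrophaceae
#' relative abundances, anaerobic methanotrophs (ANME) are an order of
#' magnitude more abundant in edges, and aerobic methanotrophs occur only in
#' the shallowest depth stratum.
#'
#' @param seed integer seed; every generator derives its own RNG stream from
#'   it, so each artifact is independently reproducible.
#' @param lakes character vector of lake labels.
#' @param zones character vector, must be `c("edge","middle")`.
#' @param traps_per_zone bubble traps per lake-zone.
#' @param n_flux_obs flux observations per trap.
#' @param temp_range_C named list of `c(min,max)` surface-sediment
#'   temperatures (deg C) per zone; edges reach warmer water than middles.
#' @param arrhenius_slope_K named numeric, true slope of ln(flux) on 1/T(K)
#'   per zone; must be negative.
#' @param flux_at_10C named numeric, expected flux (mg CH4 m-2 d-1) at 10 deg
#'   C per zone; fixes the Arrhenius intercept `lnA = log(flux10) -
#'   slope/283.15`.
#' @param flux_noise_sdlog sd of multiplicative lognormal flux noise
#'   (ebullition is strongly right-skewed).
#' @param depth_grid_cm strictly increasing sampling depths (cm).
#' @param d13C_TOC_permil bulk organic carbon d13C (permil VPDB).
#' @param alpha_true fractionation factor of methanogenesis used by the
#'   forward model.
#' @param f_meth_profile fraction of DIC derived from methanogenesis at each
#'   depth of `depth_grid_cm`, in `[0,1]`.
#' @param DIC_uM_profile porewater DIC (uM) at each depth.
#' @param measured_CH4_fraction fraction of generated CH4 retained in
#'   porewater (the rest escapes as fugitive CH4).
#' @param conc_noise_sdlog sd(log) of lognormal noise on the measured DIC
#'   concentration (the forward mass balance stays internally consistent:
#'   porewater CH4 is computed from the noisy DIC).
#' @param isotope_noise_permil sd of Gaussian noise added to the measured
#'   d13C of CH4 and DIC; 0 gives the exact forward model.
#' @param activity_sdlog sd(log) of the latent per-sample methanogenic
#'   activity multiplier shared between the chemistry and OTU generators; it
#'   couples methanogen abundance to `f_meth` and hence porewater CH4.
#' @param n_otus total OTUs, must exceed the number of guilds.
#' @param library_size reads per sample before rarefaction.
#' @param guild_fractions data frame with columns `guild`, `edge`, `middle`:
#'   target mean relative abundance per zone.
#' @param otu_overdispersion Dirichlet-multinomial overdispersion theta in
#'   (0, 1); counts are multinomial draws from a Dirichlet with concentration
#'   `p * (1 - theta) / theta`. 0 disables the Dirichlet layer.
#' @param depth_gradient_sd sd of per-OTU log-linear depth slopes (depth is
#'   the dominant compositional axis).
#' @param zone_shift_sd sd of per-OTU log zone offsets for background taxa.
#' @param zone_effect multiplier on all zone contrasts; 0 removes every
#'   edge/middle difference (null-model mode).
#' @param replicate_pairs if `TRUE` the OTU generator emits two technical
#'   replicates per core-depth.
#' @param rarefaction_depth default per-sample depth for [rarefy_counts()].
#' @param qpcr_copies0 true 16S copies per g wet sediment extrapolated to the
#'   sediment surface.
#' @param qpcr_decay_log10_per_cm log10 decline of total copies per cm depth.
#' @param qpcr_efficiency amplification efficiency (1 = perfect doubling).
#' @param qpcr_ct_sd Gaussian Ct noise (cycles).
#' @param qpcr_sdlog lognormal spread of true copies around the depth trend.
#'
#' @return object of class `limnoch4_config` (a validated list).
#' @seealso [generate_flux_records()], [generate_core_chemistry()],
#'   [generate_otu_table()], [generate_qpcr_plate()]
#' @export
#' @examples
#' cfg <- synthetic_config(seed = 1)
#' flux <- generate_flux_records(cfg)
#' head(flux)
synthetic_config <- function(seed = 1,
                             lakes = c("MH", "IH"),
                             zones = c("edge", "middle"),
                             traps_per_zone = 3,
                             n_flux_obs = 200,
                             temp_range_C = list(edge = c(4, 22),
                                                 middle = c(4, 14)),
                             arrhenius_slope_K = c(edge = -5000,
                                                   middle = -17500),
                             flux_at_10C = c(edge = 25, middle = 5),
                             flux_noise_sdlog = 1,
                             depth_grid_cm = seq(4, 40, by = 4),
                             d13C_TOC_permil = -28,
                             alpha_true = 1.060,
                             f_meth_profile = NULL,
                             DIC_uM_profile = NULL,
                             measured_CH4_fraction = 0.3,
                             conc_noise_sdlog = 0.15,
                             isotope_noise_permil = 0.5,
                             activity_sdlog = 0.4,
                             n_otus = 150,
                             library_size = 5000,
                             guild_fractions = NULL,
                             otu_overdispersion = 0.02,
                             depth_gradient_sd = 1,
                             zone_shift_sd = 0.5,
                             zone_effect = 1,
                             replicate_pairs = FALSE,
                             rarefaction_depth = 3000,
                             qpcr_copies0 = 1e9,
                             qpcr_decay_log10_per_cm = 0.04,
                             qpcr_efficiency = 1,
                             qpcr_ct_sd = 0.15,
                             qpcr_sdlog = 0.2) {
  nd <- length(depth_grid_cm)
  if (is.null(f_meth_profile)) {
    f_meth_profile <- seq(0.2, 0.7, length.out = nd)
  }
  if (is.null(DIC_uM_profile)) {
    # saturating diagenetic shape: steep accumulation near the surface
    DIC_uM_profile <- 500 + 2500 *
      sqrt(depth_grid_cm / max(depth_grid_cm))
  }
  if (is.null(guild_fractions)) {
    guild_fractions <- data.frame(
      guild = c("methanogen", "syntrophaceae", "ANME",
                "aerobic_methanotroph"),
      edge = c(0.005, 0.005, 0.003, 0.005),
      middle = c(0.015, 0.015, 0.0003, 0.005)
    )
  }
  cfg <- list(
    seed = seed, lakes = lakes, zones = zones,
    traps_per_zone = traps_per_zone, n_flux_obs = n_flux_obs,
    temp_range_C = temp_range_C, arrhenius_slope_K = arrhenius_slope_K,
    flux_at_10C = flux_at_10C,
    arrhenius_lnA = log(flux_at_10C) - arrhenius_slope_K / 283.15,
    flux_noise_sdlog = flux_noise_sdlog,
    depth_grid_cm = depth_grid_cm,
    d13C_TOC_permil = d13C_TOC_permil, alpha_true = alpha_true,
    f_meth_profile = f_meth_profile, DIC_uM_profile = DIC_uM_profile,
    measured_CH4_fraction = measured_CH4_fraction,
    conc_noise_sdlog = conc_noise_sdlog,
    isotope_noise_permil = isotope_noise_permil,
    activity_sdlog = activity_sdlog,
    n_otus = n_otus, library_size = library_size,
    guild_fractions = guild_fractions,
    otu_overdispersion = otu_overdispersion,
    depth_gradient_sd = depth_gradient_sd,
    zone_shift_sd = zone_shift_sd, zone_effect = zone_effect,
    replicate_pairs = replicate_pairs,
    rarefaction_depth = rarefaction_depth,
    qpcr_copies0 = qpcr_copies0,
    qpcr_decay_log10_per_cm = qpcr_decay_log10_per_cm,
    qpcr_efficiency = qpcr_efficiency, qpcr_ct_sd = qpcr_ct_sd,
    qpcr_sdlog = qpcr_sdlog
  )
  validate_config(cfg)
  class(cfg) <- "limnoch4_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.numeric(cfg$seed), length(cfg$seed) == 1L)
  if (!identical(sort(cfg$zones), c("edge", "middle"))) {
    stop("zones must be exactly {edge, middle}", call. = FALSE)
  }
  if (cfg$traps_per_zone < 1 || cfg$n_flux_obs < 1) {
    stop("configuration error: need at least one trap and one observation",
         call. = FALSE)
  }
  if (any(cfg$arrhenius_slope_K >= 0)) {
    stop("arrhenius_slope_K must be negative", call. = FALSE)
  }
  if (any(diff(cfg$depth_grid_cm) <= 0)) {
    stop("depth_grid_cm must be strictly increasing", call. = FALSE)
  }
  fr <- c(cfg$f_meth_profile, cfg$measured_CH4_fraction,
          unlist(cfg$guild_fractions[c("edge", "middle")]))
  if (any(fr < 0 | fr > 1)) {
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (length(cfg$f_meth_profile) != length(cfg$depth_grid_cm) ||
      length(cfg$DIC_uM_profile) != length(cfg$depth_grid_cm)) {
    stop("f_meth_profile and DIC_uM_profile must match depth_grid_cm",
         call. = FALSE)
  }
  if (cfg$n_otus < nrow(cfg$guild_fractions)) {
    stop("n_otus must be at least the number of guilds", call. = FALSE)
  }
  if (cfg$otu_overdispersion < 0 || cfg$otu_overdispersion >= 1) {
    stop("otu_overdispersion must be in [0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.limnoch4_config <- function(x, ...) {
  cat("<limnoch4 synthetic study config>\n")
  cat("  seed:", x$seed, " lakes:", paste(x$lakes, collapse = "/"),
      " zones:", paste(x$zones, collapse = "/"), "\n")
  cat("  flux: ", x$traps_per_zone, " traps/zone x ", x$n_flux_obs,
      " obs; slopes (K): edge ", x$arrhenius_slope_K[["edge"]],
      ", middle ", x$arrhenius_slope_K[["middle"]], "\n", sep = "")
  cat("  cores: ", length(x$lakes) * length(x$zones), " x ",
      length(x$depth_grid_cm), " depths (",
      min(x$depth_grid_cm), "-", max(x$depth_grid_cm), " cm)\n", sep = "")
  cat("  OTUs:", x$n_otus, " library:", x$library_size,
      " rarefaction:", x$rarefaction_depth, "\n")
  invisible(x)
}
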