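# Synthetic study generators. Each artifact draws from its own RNG stream
# derived from cfg$seed (streams: 1 flux, 2 chemistry, 3 OTU, 4 qPCR,
# 10 shared latent activity), so artifacts are independently reproducible.

# Latent per-core-depth methanogenic activity multiplier, shared between the
# chemistry and OTU generators: it scales both the fraction of DIC derived
# from methanogenesis and the methanogen/syntroph abundance targets, which is
# what couples porewater CH4 to the community.
latent_activity <- function(cfg) {
  cores <- expand.grid(lake = cfg$lakes, zone = cfg$zones,
                       stringsAsFactors = FALSE)
  grid <- merge(cores, data.frame(depth_cm = cfg$depth_grid_cm))
  grid <- grid[order(grid$lake, grid$zone, grid$depth_cm), ]
  grid$activity <- with_stream(cfg$seed, 10L,
                               rlnorm(nrow(grid), 0, cfg$activity_sdlog))
  zs <- ifelse(grid$zone == "middle", 0.25, -0.25) * cfg$zone_effect
  grid$activity <- grid$activity * exp(zs)
  grid$sample <- sample_id(grid$lake, grid$zone, grid$depth_cm)
  grid
}

sample_id <- function(lake, zone, depth_cm) {
  paste0(lake, toupper(substr(zone, 1, 1)), depth_cm)
}

#' Generate synthetic bubble-trap flux records
#'
#' Draws, for every trap in every lake zone, surface-sediment temperatures
#' uniform on the zone's range and fluxes from the zone's Arrhenius law
#' `flux = exp(lnA + slope / T_K)` multiplied by lognormal noise. Dates are
#' spread over six ice-free seasons (June-September).
#'
#' @param cfg a [synthetic_config()].
#' @return data frame with columns `trap_id`, `lake`, `zone`, `date`,
#'   `temp_C`, `flux_mg_m2_d`.
#' @export
generate_flux_records <- function(cfg) {
  validate_config(cfg)
  with_stream(cfg$seed, 1L, {
    out <- list()
    seasons <- as.Date(unlist(lapply(2009:2014, function(y) {
      seq(as.Date(sprintf("%d-06-01", y)), as.Date(sprintf("%d-09-30", y)),
          by = "day")
    })), origin = "1970-01-01")
    for (lake in cfg$lakes) {
      for (zone in cfg$zones) {
        rng <- cfg$temp_range_C[[zone]]
        slope <- cfg$arrhenius_slope_K[[zone]]
        lnA <- cfg$arrhenius_lnA[[zone]]
        for (trap in seq_len(cfg$traps_per_zone)) {
          n <- cfg$n_flux_obs
          temp <- runif(n, rng[1], rng[2])
          mu <- exp(lnA + slope / (temp + 273.15))
          noise <- if (cfg$flux_noise_sdlog > 0) {
            rlnorm(n, 0, cfg$flux_noise_sdlog)
          } else {
            rep(1, n)
          }
          out[[length(out) + 1L]] <- data.frame(
            trap_id = sprintf("%s-%s-T%d", lake, zone, trap),
            lake = lake, zone = zone,
            date = sort(sample(seasons, n, replace = TRUE)),
            temp_C = temp,
            flux_mg_m2_d = mu * noise
          )
        }
      }
    }
    do.call(rbind, out)
  })
}

#' Generate synthetic depth-resolved core geochemistry
#'
#' Runs the forward stable carbon isotope mass balance at every core depth:
#' `d13C_CH4 = (d13C_TOC + 1000)/alpha - 1000`, methanogenic CO2 endmember
#' `d13C_CO2meth = 2 d13C_TOC - d13C_CH4` (1:1 CH4:CO2 mass balance on the
#' substrate), and `d13C_DIC = f * d13C_CO2meth + (1 - f) * d13C_TOC`, where
#' `f` is the depth profile of the methanogenic DIC fraction scaled by the
#' latent per-sample activity. Porewater CH4 retains
#' `measured_CH4_fraction * f * DIC`; the remainder is the fugitive pool the
#' inverse model ([fugitive_ch4()]) reconstructs. Gaussian noise
#' (`isotope_noise_permil`) is optionally added to the measured CH4 and DIC
#' isotope ratios; with zero noise the inverse recovers `f` exactly.
#'
#' @param cfg a [synthetic_config()].
#' @return data frame with one row per core-depth and columns `sample`,
#'   `core`, `lake`, `zone`, `depth_cm`, `TOC_pct`, `d13C_TOC`, `CH4_uM`,
#'   `DIC_uM`, `d13C_CH4`, `d13C_DIC`, `S_pct`, `TOC_TS`, plus the true
#'   generating `f_meth_true`.
#' @export
generate_core_chemistry <- function(cfg) {
  validate_config(cfg)
  act <- latent_activity(cfg)
  nd <- length(cfg$depth_grid_cm)
  prof <- data.frame(depth_cm = cfg$depth_grid_cm,
                     f_base = cfg$f_meth_profile,
                     DIC_uM = cfg$DIC_uM_profile)
  chem <- merge(act, prof, by = "depth_cm")
  chem <- chem[order(chem$lake, chem$zone, chem$depth_cm), ]
  with_stream(cfg$seed, 2L, {
    n <- nrow(chem)
    zfac <- ifelse(chem$zone == "middle", 1.15, 0.9)
    f <- pmin(pmax(chem$f_base * chem$activity *
                     zfac^cfg$zone_effect, 0), 0.95)
    noise <- cfg$isotope_noise_permil
    dic_uM <- chem$DIC_uM * rlnorm(n, 0, cfg$conc_noise_sdlog)
    toc_iso <- cfg$d13C_TOC_permil + rnorm(n, 0, 0.3 * noise)
    ch4_true <- (toc_iso + 1000) / cfg$alpha_true - 1000
    co2meth <- 2 * toc_iso - ch4_true
    dic_true <- f * co2meth + (1 - f) * toc_iso
    # TOC higher in the IH middle, edge sediments slightly coarser in S
    toc_pct <- 8 + 2 * (chem$lake == "IH" & chem$zone == "middle") -
      0.04 * chem$depth_cm + rnorm(n, 0, 0.5)
    s_pct <- pmax(0.3 + 0.005 * chem$depth_cm + rnorm(n, 0, 0.05), 0.05)
    data.frame(
      sample = chem$sample,
      core = paste(chem$lake, chem$zone, sep = "-"),
      lake = chem$lake, zone = chem$zone, depth_cm = chem$depth_cm,
      TOC_pct = toc_pct,
      d13C_TOC = toc_iso,
      CH4_uM = cfg$measured_CH4_fraction * f * dic_uM,
      DIC_uM = dic_uM,
      d13C_CH4 = ch4_true + rnorm(n, 0, noise),
      d13C_DIC = dic_true + rnorm(n, 0, noise),
      S_pct = s_pct,
      TOC_TS = toc_pct / s_pct,
      f_meth_true = f
    )
  })
}

# taxonomy template strings; guild members must resolve through the default
# guild map (ANME lineages sit inside Methanosarcinales, so the map matches
# ANME patterns first)
guild_taxonomy <- list(
  methanogen = c(
    "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanoregulaceae;Methanoregula",
    "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosaetaceae;Methanosaeta",
    "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobacterium",
    "Archaea;Euryarchaeota;Thermoplasmata;Methanomassiliicoccales;Methanomassiliicoccaceae;Methanomassiliicoccus",
    "Archaea;Euryarchaeota;Methanomicrobia;Methanocellales;Methanocellaceae;Methanocella",
    "Archaea;Euryarchaeota;Methanococci;Methanococcales;Methanococcaceae;Methanococcus"),
  syntrophaceae = c(
    "Bacteria;Proteobacteria;Deltaproteobacteria;Syntrophobacterales;Syntrophaceae;Smithella",
    "Bacteria;Proteobacteria;Deltaproteobacteria;Syntrophobacterales;Syntrophaceae;Syntrophus",
    "Bacteria;Proteobacteria;Deltaproteobacteria;Syntrophobacterales;Syntrophaceae;uncultured"),
  ANME = c(
    "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;ANME-2d;ANME-2d",
    "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;ANME-2a-2b;ANME-2b",
    "Archaea;Euryarchaeota;Methanomicrobia;ANME-1;ANME-1b;ANME-1b"),
  aerobic_methanotroph = c(
    "Bacteria;Proteobacteria;Gammaproteobacteria;Methylococcales;Methylococcaceae;Methylobacter",
    "Bacteria;Proteobacteria;Gammaproteobacteria;Methylococcales;Methylococcaceae;Methylomonas",
    "Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Methylocystaceae;Methylocystis")
)

background_lineages <- c(
  "Bacteria;Proteobacteria;Deltaproteobacteria",
  "Bacteria;Proteobacteria;Betaproteobacteria",
  "Bacteria;Proteobacteria;Gammaproteobacteria;Xanthomonadales",
  "Bacteria;Chloroflexi;Anaerolineae",
  "Bacteria;Chloroflexi;Dehalococcoidia",
  "Bacteria;Bacteroidetes;Bacteroidia",
  "Bacteria;Acidobacteria;Acidobacteria_Gp1",
  "Bacteria;Planctomycetes;Phycisphaerae",
  "Bacteria;Planctomycetes;Planctomycetia",
  "Bacteria;Aminicenantes;Aminicenantia",
  "Archaea;Euryarchaeota;Thermoplasmata;Thermoplasmatales",
  "Bacteria;Verrucomicrobia;Verrucomicrobiae",
  "Bacteria;Actinobacteria;Actinobacteria",
  "Bacteria;Firmicutes;Clostridia",
  "Bacteria;Spirochaetes;Spirochaetia",
  "Bacteria;Nitrospirae;Nitrospira",
  "Bacteria;Atribacteria;Atribacteria",
  "Bacteria;Caldiserica;Caldisericia"
)

#' Generate a synthetic OTU table with guild, depth, and zone structure
#'
#' Counts are multinomial draws (library size `cfg$library_size`) from a
#' Dirichlet-perturbed mean composition. Background OTUs carry log-linear
#' depth gradients (depth is the dominant compositional axis) and, for
#' middles, log-normal zone offsets. Guild OTUs (methanogens, Syntrophaceae,
#' ANME, aerobic methanotrophs) are pinned to zone-specific target relative
#' abundances: methanogens and syntrophs higher in middles (scaled by the
#' shared latent activity), ANME roughly an order of magnitude higher in
#' edges, and aerobic methanotrophs present only in the shallowest depth
#' stratum. `cfg$zone_effect = 0` removes every edge/middle contrast.
#'
#' @param cfg a [synthetic_config()].
#' @return object of class `limnoch4_otu`: list with `counts` (samples x
#'   OTUs integer matrix), `taxonomy` (named character, semicolon-delimited
#'   lineages), and `meta` (per-sample data frame with `sample`, `core`,
#'   `lake`, `zone`, `depth_cm`, `replicate_group`).
#' @export
generate_otu_table <- function(cfg) {
  validate_config(cfg)
  act <- latent_activity(cfg)
  gf <- cfg$guild_fractions
  guilds <- gf$guild
  with_stream(cfg$seed, 3L, {
    members <- lapply(guilds, function(g) {
      tax <- guild_taxonomy[[g]]
      if (is.null(tax)) tax <- paste0("Bacteria;Unknown;", g)
      tax
    })
    names(members) <- guilds
    n_guild <- sum(lengths(members))
    n_bg <- cfg$n_otus - n_guild
    if (n_bg < 1) stop("n_otus too small for the guild inventory")
    bg_lineage <- sample(background_lineages, n_bg, replace = TRUE)
    bg_tax <- sprintf("%s;Order_%03d;Family_%03d;Genus_%03d", bg_lineage,
                      seq_len(n_bg), seq_len(n_bg), seq_len(n_bg))
    taxonomy <- c(unlist(members, use.names = FALSE), bg_tax)
    otu_ids <- sprintf("OTU_%d", seq_along(taxonomy))
    names(taxonomy) <- otu_ids
    guild_of <- c(rep(guilds, lengths(members)), rep(NA, n_bg))

    # within-guild split weights and background structure, drawn once
    split_w <- lapply(guilds, function(g) {
      w <- rlnorm(length(members[[g]]), 0, 0.5)
      w / sum(w)
    })
    names(split_w) <- guilds
    bg_w <- rlnorm(n_bg, 0, 1.5)
    bg_depth <- rnorm(n_bg, 0, cfg$depth_gradient_sd)
    bg_zone <- rnorm(n_bg, 0, cfg$zone_shift_sd) * cfg$zone_effect

    ds <- (act$depth_cm - mean(cfg$depth_grid_cm)) /
      max(1, sd(cfg$depth_grid_cm))
    theta <- cfg$otu_overdispersion
    shallowest <- min(cfg$depth_grid_cm)
    reps <- if (isTRUE(cfg$replicate_pairs)) c("a", "b") else ""

    counts <- list()
    meta <- list()
    for (i in seq_len(nrow(act))) {
      zone <- act$zone[i]
      # zone_effect interpolates each guild target between the zone value
      # and the edge/middle average (null design at zone_effect = 0)
      tgt <- vapply(seq_along(guilds), function(k) {
        avg <- mean(c(gf$edge[k], gf$middle[k]))
        zonal <- gf[[zone]][k]
        avg + cfg$zone_effect * (zonal - avg)
      }, numeric(1))
      names(tgt) <- guilds
      if ("methanogen" %in% guilds) {
        tgt["methanogen"] <- tgt["methanogen"] * act$activity[i]
      }
      if ("syntrophaceae" %in% guilds) {
        tgt["syntrophaceae"] <- tgt["syntrophaceae"] * act$activity[i]
      }
      if ("aerobic_methanotroph" %in% guilds &&
          act$depth_cm[i] > shallowest) {
        tgt["aerobic_methanotroph"] <- 0
      }
      tgt <- pmin(tgt, 0.2)
      guild_p <- unlist(lapply(guilds, function(g) {
        split_w[[g]] * tgt[[g]]
      }))
      bg <- bg_w * exp(bg_depth * ds[i] +
                         if (zone == "middle") bg_zone else 0)
      bg <- bg / sum(bg) * (1 - sum(guild_p))
      p <- c(guild_p, bg)
      for (r in reps) {
        if (theta > 0) {
          conc <- p * (1 - theta) / theta
          g <- rgamma(length(conc), shape = conc)
          pd <- if (sum(g) > 0) g / sum(g) else p
        } else {
          pd <- p
        }
        counts[[length(counts) + 1L]] <-
          as.integer(rmultinom(1, cfg$library_size, pd))
        meta[[length(meta) + 1L]] <- data.frame(
          sample = paste0(act$sample[i], r),
          core = paste(act$lake[i], act$zone[i], sep = "-"),
          lake = act$lake[i], zone = zone, depth_cm = act$depth_cm[i],
          replicate_group = act$sample[i]
        )
      }
    }
    counts <- do.call(rbind, counts)
    meta <- do.call(rbind, meta)
    rownames(counts) <- meta$sample
    colnames(counts) <- otu_ids
    structure(list(counts = counts, taxonomy = taxonomy, meta = meta,
                   guild_of = setNames(guild_of, otu_ids)),
              class = "limnoch4_otu")
  })
}

#' @export
print.limnoch4_otu <- function(x, ...) {
  cat("<limnoch4 OTU table> ", nrow(x$counts), " samples x ",
      ncol(x$counts), " OTUs; median library ",
      stats::median(rowSums(x$counts)), "\n", sep = "")
  invisible(x)
}

#' Generate a synthetic qPCR plate
#'
#' Standards follow a log-linear Ct versus log10(copies/uL) curve with slope
#' `-1/log10(1 + efficiency)` (-3.32 cycles per decade at perfect
#' efficiency), evaluated at the configured dilution series of the genomic
#' DNA stock. Sample Cts are back-computed from true 16S copies per g wet
#' sediment that decline log-linearly with depth, assuming 0.25 g extracted
#' into 100 uL and a 1/100 template dilution.
#'
#' @param cfg a [synthetic_config()].
#' @param standard a [qpcr_standard()] describing the stock.
#' @return list of class `limnoch4_qpcr_plate` with `standards` (dilution,
#'   copies_per_uL, Ct), `samples` (sample, core, depth_cm, dilution, Ct),
#'   `truth` (true copies per g), and the extraction constants used.
#' @export
generate_qpcr_plate <- function(cfg, standard = qpcr_standard()) {
  validate_config(cfg)
  if (cfg$qpcr_efficiency <= 0) stop("qPCR efficiency must be positive")
  act <- latent_activity(cfg)
  slope <- -1 / log10(1 + cfg$qpcr_efficiency)
  intercept <- 38  # Ct of a single template copy per uL
  elution_uL <- 100
  mass_g <- 0.25
  sample_dilution <- 100
  with_stream(cfg$seed, 4L, {
    std_copies <- standard_copies_per_uL(standard)
    standards <- data.frame(
      dilution = standard$dilutions,
      copies_per_uL = std_copies,
      Ct = intercept + slope * log10(std_copies) +
        rnorm(length(std_copies), 0, cfg$qpcr_ct_sd)
    )
    truth <- data.frame(
      sample = act$sample, core = paste(act$lake, act$zone, sep = "-"),
      depth_cm = act$depth_cm,
      copies_per_g = cfg$qpcr_copies0 *
        10^(-cfg$qpcr_decay_log10_per_cm * act$depth_cm) *
        rlnorm(nrow(act), 0, cfg$qpcr_sdlog)
    )
    template <- truth$copies_per_g * mass_g / elution_uL / sample_dilution
    samples <- data.frame(
      sample = truth$sample, core = truth$core, depth_cm = truth$depth_cm,
      dilution = sample_dilution,
      Ct = intercept + slope * log10(template) +
        rnorm(nrow(truth), 0, cfg$qpcr_ct_sd)
    )
    structure(list(standards = standards, samples = samples, truth = truth,
                   elution_uL = elution_uL, mass_g = mass_g),
              class = "limnoch4_qpcr_plate")
  })
}
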