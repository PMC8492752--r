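# End-to-end orchestration: flux -> isotopes -> community -> prediction,
# with input schema validation and a JSON-serializable report.

#' Validate pipeline input files
#'
#' Schema checks for the CSV/TSV interchange formats (required columns,
#' value ranges) and cross-file sample-key consistency. A missing optional
#' column downgrades the affected stage to "skippable" rather than failing
#' the whole run.
#'
#' @param paths named list with any of `flux`, `chem`, `otu`, `meta`
#'   (file paths).
#' @return list of class `limnoch4_validation`: per-file `issues`
#'   (character vectors), `skippable_stages`, and `ok` (no blocking issue).
#' @export
validate_inputs <- function(paths) {
  issues <- list()
  skippable <- character()
  samples <- list()
  if (!is.null(paths$flux)) {
    prob <- character()
    if (!file.exists(paths$flux)) {
      prob <- "file not found"
    } else {
      fx <- read_flux_csv(paths$flux)
      need <- c("lake", "zone", "temp_C", "flux_mg_m2_d")
      miss <- setdiff(need, names(fx))
      if (length(miss)) {
        prob <- c(prob, paste("missing columns:",
                              paste(miss, collapse = ", ")))
      } else {
        if (any(fx$flux_mg_m2_d < 0)) prob <- c(prob, "negative fluxes")
        if (any(fx$temp_C < -5 | fx$temp_C > 40)) {
          prob <- c(prob, "temperatures outside -5..40 C")
        }
      }
    }
    issues$flux <- prob
  }
  if (!is.null(paths$chem)) {
    prob <- character()
    if (!file.exists(paths$chem)) {
      prob <- "file not found"
    } else {
      ch <- read_chem_csv(paths$chem)
      need <- c("sample", "depth_cm", "CH4_uM", "DIC_uM")
      miss <- setdiff(need, names(ch))
      if (length(miss)) {
        prob <- c(prob, paste("missing columns:",
                              paste(miss, collapse = ", ")))
      } else {
        samples$chem <- ch$sample
        iso <- c("d13C_TOC", "d13C_CH4", "d13C_DIC")
        iso_miss <- setdiff(iso, names(ch))
        if (length(iso_miss)) {
          skippable <- c(skippable, "isotope_partition")
          issues$chem_note <- paste("isotope stage skippable; missing:",
                                    paste(iso_miss, collapse = ", "))
        } else if (any(ch[iso] <= -120 | ch[iso] >= 30, na.rm = TRUE)) {
          prob <- c(prob, "delta13C values outside (-120, 30) permil")
        }
        if (any(ch$CH4_uM < 0 | ch$DIC_uM < 0, na.rm = TRUE)) {
          prob <- c(prob, "negative concentrations")
        }
      }
    }
    issues$chem <- prob
  }
  if (!is.null(paths$otu)) {
    prob <- character()
    if (!file.exists(paths$otu)) {
      prob <- "file not found"
    } else {
      ot <- read_otu_tsv(paths$otu, meta_path = paths$meta)
      if (any(is.na(ot$counts)) || any(ot$counts < 0)) {
        prob <- c(prob, "negative or missing counts")
      }
      if (anyDuplicated(colnames(ot$counts))) {
        prob <- c(prob, "duplicate OTU ids")
      }
      samples$otu <- rownames(ot$counts)
    }
    issues$otu <- prob
  }
  if (length(samples) == 2) {
    mism <- c(setdiff(samples$otu, samples$chem),
              setdiff(samples$chem, samples$otu))
    if (length(mism)) {
      issues$cross <- paste("sample keys not shared between OTU and",
                            "chemistry:", paste(mism, collapse = ", "))
    }
  }
  blocking <- unlist(issues[setdiff(names(issues), "chem_note")])
  structure(list(issues = issues, skippable_stages = unique(skippable),
                 ok = length(blocking) == 0),
            class = "limnoch4_validation")
}

#' Run the full analysis pipeline
#'
#' Executes, on synthetic inputs generated from `cfg` (or on files read
#' from `paths`): flux binning + Arrhenius fits + pairwise slope
#' comparisons on all robustness subsets; the isotope mass balance and
#' pathway classification; community statistics (rarefaction, replicate
#' averaging if present, Bray-Curtis, PCoA, PERMANOVA by zone and lake,
#' Mantel vs depth, guild abundances, qPCR quantification, absolute guild
#' proxy, fugitive-CH4 correlation); and the PLSR/MLR suite comparison.
#' All seeds derive from `cfg$seed` and are recorded in the report.
#'
#' @param cfg a [synthetic_config()] (synthetic mode), or `NULL` with
#'   `paths` given (file mode; `paths` as in [validate_inputs()], and a
#'   `seed` element controls the permutation streams).
#' @param paths optional named list of input files (exactly one of `cfg` /
#'   `paths` drives the inputs).
#' @param out_dir if non-NULL, CSV artifacts and `report.json` are written
#'   there.
#' @param n_perm permutations for PERMANOVA/Mantel.
#' @return report list of class `limnoch4_report`.
#' @export
run_pipeline <- function(cfg = synthetic_config(), paths = NULL,
                         out_dir = NULL, n_perm = 999) {
  if (!is.null(paths) && !is.null(cfg) &&
      !inherits(cfg, "limnoch4_config")) {
    stop("exactly one of cfg / paths must drive the inputs")
  }
  if (is.null(paths)) {
    flux <- generate_flux_records(cfg)
    chem <- generate_core_chemistry(cfg)
    otu <- generate_otu_table(cfg)
    plate <- generate_qpcr_plate(cfg)
    seed <- cfg$seed
    rarefaction_depth <- cfg$rarefaction_depth
  } else {
    val <- validate_inputs(paths)
    if (!val$ok) {
      stop("input validation failed: ",
           paste(unlist(val$issues), collapse = "; "))
    }
    flux <- if (!is.null(paths$flux)) read_flux_csv(paths$flux)
    chem <- if (!is.null(paths$chem)) read_chem_csv(paths$chem)
    otu <- if (!is.null(paths$otu)) {
      read_otu_tsv(paths$otu, meta_path = paths$meta)
    }
    plate <- if (!is.null(paths$qpcr)) read_qpcr_csv(paths$qpcr)
    seed <- paths$seed %||% 1
    rarefaction_depth <- paths$rarefaction_depth %||% 3000
  }
  report <- list(seeds = list(master = seed))

  # --- flux & temperature ---
  bins <- bin_flux(flux)
  fits <- fit_arrhenius(bins)
  comparisons <- do.call(rbind, lapply(
    c("full", "edge_trimmed", "drop_top_middle_bin",
      "drop_bottom_middle_bin"),
    function(s) compare_slopes(bins, subset = s)))
  report$flux <- list(bins = bins, arrhenius = fits,
                      comparisons = comparisons)

  # --- isotope partition ---
  fug <- fugitive_ch4(chem)
  report$isotopes <- list(
    fugitive = fug,
    dominant_pathway = names(which.max(table(fug$pathway))),
    n_flagged = sum(fug$f_clipped | fug$negative_fugitive | fug$undefined))

  # --- community ---
  rar <- rarefy_counts(otu, depth = rarefaction_depth, seed = seed)
  if (length(unique(rar$meta$replicate_group)) < nrow(rar$counts)) {
    rar <- average_replicates(rar)
  }
  dm <- bray_curtis(rar)
  ord <- pcoa(dm)
  meta <- rar$meta[match(rownames(rar$counts), rar$meta$sample), ]
  perm_zone <- permanova(dm, meta$zone, n_perm = n_perm, seed = seed)
  perm_lake <- permanova(dm, meta$lake, n_perm = n_perm, seed = seed)
  mantel_depth <- mantel_test(dm, stats::dist(meta$depth_cm),
                              n_perm = n_perm, seed = seed)
  guilds <- read_guild_map()
  ga <- guild_abundance(rar, guilds)
  qp <- quantify_qpcr(plate)
  proxy <- absolute_guild_proxy(ga$abundance, qp$samples)
  fug_cor <- correlate_fugitive_with_microbes(fug, rar, n_perm = n_perm,
                                              seed = seed)
  report$community <- list(
    pcoa_pct_variation = head(ord$pct_variation, 3),
    permanova_zone = unclass(perm_zone),
    permanova_lake = unclass(perm_lake),
    mantel_depth = mantel_depth,
    guild_abundance = ga,
    qpcr_curve = qp$curve,
    absolute_proxy_tests = proxy$tests,
    fugitive_mantel = fug_cor$mantel,
    fugitive_top_lineages = head(fug_cor$lineages, 5))

  # --- porewater CH4 models ---
  chem_m <- chem[match(rownames(rar$counts), chem$sample), , drop = FALSE]
  vm <- assemble_variables(rar, chem_m, guilds = guilds)
  models <- compare_models(vm)
  report$models <- list(comparison = models, n_variables = ncol(vm$X))

  class(report) <- "limnoch4_report"
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_flux_csv(flux, file.path(out_dir, "flux.csv"))
    write_chem_csv(chem, file.path(out_dir, "chem.csv"))
    write_chem_csv(fug, file.path(out_dir, "fugitive.csv"))
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

report_to_json <- function(report) {
  strip <- function(x) {
    if (inherits(x, "data.frame")) return(x)
    if (is.list(x)) return(lapply(unclass(x), strip))
    x
  }
  strip(report)
}

#' @export
print.limnoch4_report <- function(x, ...) {
  cat("<limnoch4 pipeline report>\n")
  f <- x$flux$arrhenius
  cat("  Arrhenius slopes (K):\n")
  for (i in seq_len(nrow(f))) {
    cat(sprintf("    %s %-6s %9.0f (se %.0f, r2 %.2f)\n", f$lake[i],
                f$zone[i], f$slope_K[i], f$se_slope[i], f$r2[i]))
  }
  cat("  dominant methanogenic pathway:", x$isotopes$dominant_pathway,
      "\n")
  cat(sprintf("  PERMANOVA edge vs middle p = %.4g; lake p = %.4g\n",
              x$community$permanova_zone$p, x$community$permanova_lake$p))
  m <- x$models$comparison
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  PLSR %-15s r2 = %.3f (%d comps, %d vars)\n",
                m$suite[i], m$plsr_r2[i], m$plsr_ncomp[i], m$n_vars[i]))
  }
  invisible(x)
}
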