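# Prediction of porewater CH4 from abiotic variables and microbial
# abundances: variable assembly, NIPALS partial least squares regression
# with VIP scores (authored here; the response is univariate), and multiple
# linear regression, plus the suite-comparison report.

#' Assemble the explanatory-variable matrix
#'
#' Builds the samples-by-variables matrix used by [fit_plsr()] and
#' [fit_mlr()] from matched OTU and chemistry tables. Blocks (provenance
#' tags): `abiotic` (depth, TOC, d13C_TOC, DIC, S, TOC:TS; CH4-derived
#' measurements are deliberately excluded as confounders of the response),
#' `otu_gt1pct` (relative abundance of every OTU exceeding 1% in at least
#' one sample, strict inequality), `lineage_sum` (summed relative abundances
#' at phylum level, selected lineages at class level), `guild_sum`
#' (functional-guild sums), and `mag_lineage_sum` (summed abundance proxies
#' for genome bins, by OTU id or lineage pattern). Identical duplicate
#' columns are collapsed with a warning. The response is porewater CH4 (uM).
#'
#' @param otu a `limnoch4_otu` whose sample ids match `chem$sample`.
#' @param chem core geochemistry data frame (see
#'   [generate_core_chemistry()] / [read_chem_csv()]).
#' @param guilds guild map for the `guild_sum` block (`NULL` to skip).
#' @param mag_map named list describing genome-bin proxies; each element is
#'   `list(otu = "OTU_id")` or `list(pattern = "lineage substring")`.
#'   `NULL` skips the block.
#' @param otu_threshold_pct inclusion threshold for single OTUs (strict >).
#' @param lineage_level,class_override passed to [lineage_sums()].
#' @return list of class `variable_matrix`: `X` (numeric matrix), `y`
#'   (response, uM CH4), `provenance` (tag per column), `samples`.
#' @export
assemble_variables <- function(otu, chem,
                               guilds = read_guild_map(),
                               mag_map = default_mag_map(),
                               otu_threshold_pct = 1,
                               lineage_level = 2,
                               class_override = c("Proteobacteria",
                                                  "Planctomycetes",
                                                  "Chloroflexi",
                                                  "Euryarchaeota",
                                                  "Firmicutes")) {
  counts <- counts_of(otu)
  unmatched <- c(setdiff(rownames(counts), chem$sample),
                 setdiff(chem$sample, rownames(counts)))
  if (length(unmatched)) {
    stop("unmatched sample keys between OTU table and chemistry: ",
         paste(unique(unmatched), collapse = ", "))
  }
  chem <- chem[match(rownames(counts), chem$sample), , drop = FALSE]
  abiotic <- cbind(depth = chem$depth_cm, TOC = chem$TOC_pct,
                   d13C_TOC = chem$d13C_TOC, DIC = chem$DIC_uM,
                   S = chem$S_pct, TOC_TS = chem$TOC_TS)
  rel <- sweep(counts, 1, rowSums(counts), "/") * 100
  blocks <- list(abiotic = abiotic)
  keep <- apply(rel, 2, max) > otu_threshold_pct
  if (any(keep)) blocks$otu_gt1pct <- rel[, keep, drop = FALSE]
  tax <- if (inherits(otu, "limnoch4_otu")) otu$taxonomy else NULL
  if (!is.null(tax)) {
    blocks$lineage_sum <- lineage_sums(counts, tax, level = lineage_level,
                                       class_override = class_override)
    if (!is.null(mag_map) && length(mag_map)) {
      mag <- vapply(names(mag_map), function(nm) {
        spec <- mag_map[[nm]]
        if (!is.null(spec$otu)) {
          if (!spec$otu %in% colnames(rel)) return(rep(NA_real_, nrow(rel)))
          rel[, spec$otu]
        } else {
          hit <- grepl(tolower(spec$pattern), tolower(tax[colnames(rel)]),
                       fixed = TRUE)
          if (!any(hit)) return(rep(NA_real_, nrow(rel)))
          rowSums(rel[, hit, drop = FALSE])
        }
      }, numeric(nrow(rel)))
      mag <- mag[, colSums(is.na(mag)) == 0, drop = FALSE]
      if (ncol(mag)) blocks$mag_lineage_sum <- mag
    }
    if (!is.null(guilds)) {
      ga <- suppressWarnings(guild_abundance(otu, guilds))
      gs <- as.matrix(ga$abundance[, names(guilds), drop = FALSE])
      rownames(gs) <- ga$abundance$sample
      blocks$guild_sum <- gs[rownames(counts), , drop = FALSE]
    }
  }
  X <- do.call(cbind, blocks)
  provenance <- rep(names(blocks), vapply(blocks, ncol, integer(1)))
  dup <- duplicated(t(X))
  if (any(dup)) {
    warning("collapsing ", sum(dup), " duplicate column(s): ",
            paste(colnames(X)[dup], collapse = ", "))
    X <- X[, !dup, drop = FALSE]
    provenance <- provenance[!dup]
  }
  structure(list(X = X, y = chem$CH4_uM, provenance = provenance,
                 samples = rownames(counts)),
            class = "variable_matrix")
}

#' Default genome-bin abundance proxies for the synthetic community
#'
#' Lineage-pattern proxies for the bins the synthetic generator tags
#' (Syntrophaceae, Phycisphaerae, Thermoplasmatales, Aminicenantes). Edit or
#' replace for real data, where a bin may map directly to one OTU
#' (`list(otu = "OTU_4")`).
#'
#' @return named list usable as `mag_map` in [assemble_variables()].
#' @export
default_mag_map <- function() {
  list(MAG_Syntrophaceae = list(pattern = "Syntrophaceae"),
       MAG_Phycisphaerae = list(pattern = "Phycisphaerae"),
       MAG_Thermoplasmata = list(pattern = "Thermoplasmatales"),
       MAG_Aminicenantes = list(pattern = "Aminicenantes"))
}

nipals_pls1 <- function(Xs, ys, ncomp) {
  n <- nrow(Xs)
  p <- ncol(Xs)
  W <- matrix(0, p, ncomp)
  P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  E <- Xs
  f <- ys
  a <- 0
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) break
    pl <- drop(crossprod(E, t)) / tt
    qk <- sum(f * t) / tt
    E <- E - tcrossprod(t, pl)
    f <- f - qk * t
    a <- k
    W[, k] <- w
    P[, k] <- pl
    Tm[, k] <- t
    q[k] <- qk
  }
  list(W = W[, seq_len(a), drop = FALSE],
       P = P[, seq_len(a), drop = FALSE],
       T = Tm[, seq_len(a), drop = FALSE],
       q = q[seq_len(a)], ncomp = a)
}

pls1_coef <- function(fit, ncomp = fit$ncomp) {
  idx <- seq_len(ncomp)
  W <- fit$W[, idx, drop = FALSE]
  P <- fit$P[, idx, drop = FALSE]
  drop(W %*% solve(crossprod(P, W), fit$q[idx]))
}

#' Partial least squares regression (NIPALS) with VIP scores
#'
#' Columns are centered and, by default, autoscaled to unit variance;
#' zero-variance columns are dropped with a warning. Latent components are
#' extracted by NIPALS on the univariate response; unless `ncomp` is fixed,
#' the number of components minimizes the leave-one-out PRESS. The reported
#' `r2` is the squared Pearson correlation between fitted and measured
#' response (calibration); the cross-validated `q2` is also reported.
#'
#' @param x a `variable_matrix` from [assemble_variables()], or a numeric
#'   matrix (then `y` is required). Needs at least 5 samples.
#' @param y response vector (ignored when `x` is a `variable_matrix`).
#' @param ncomp `"auto"` (leave-one-out minimum PRESS) or a fixed integer.
#' @param scale autoscale columns to unit variance (centering always).
#' @param max_comp upper bound for component search.
#' @return object of class `plsr_fit`: weights `W`, scores `T`, loadings
#'   `P`, `coefficients` (original scale), `fitted`, `r2`, `q2`, `press`
#'   (per candidate ncomp), `ncomp`, `vip`, `significant_vars` (VIP > 1).
#' @export
fit_plsr <- function(x, y = NULL, ncomp = "auto", scale = TRUE,
                     max_comp = 10) {
  if (inherits(x, "variable_matrix")) {
    y <- x$y
    X <- x$X
  } else {
    X <- as.matrix(x)
  }
  if (is.null(y)) stop("response y required")
  n <- nrow(X)
  if (n < 5) stop("need at least 5 samples")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  if (ncol(X) < 1) stop("no usable explanatory variables")
  mx <- colMeans(X)
  sx <- if (scale) apply(X, 2, sd) else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y)
  ys <- y - my
  cap <- min(max_comp, n - 2, ncol(X), qr(Xs)$rank)
  press <- NULL
  if (identical(ncomp, "auto")) {
    press <- rep(0, cap)
    for (i in seq_len(n)) {
      fi <- nipals_pls1(Xs[-i, , drop = FALSE], ys[-i], cap)
      for (a in seq_len(cap)) {
        b <- pls1_coef(fi, min(a, fi$ncomp))
        pred <- sum(Xs[i, ] * b)
        press[a] <- press[a] + (ys[i] - pred)^2
      }
    }
    ncomp <- which.min(press)
  } else {
    ncomp <- min(as.integer(ncomp), cap)
  }
  fit <- nipals_pls1(Xs, ys, ncomp)
  beta_s <- pls1_coef(fit)
  fitted <- drop(Xs %*% beta_s) + my
  coefs <- beta_s / sx
  intercept <- my - sum(coefs * mx)
  ssy <- fit$q^2 * colSums(fit$T^2)
  out <- structure(list(
    W = fit$W, P = fit$P, T = fit$T, q = fit$q,
    ncomp = fit$ncomp,
    coefficients = c("(Intercept)" = intercept,
                     setNames(coefs, colnames(X))),
    fitted = fitted,
    r2 = if (var(fitted) > 0) cor(fitted, y)^2 else 0,
    q2 = if (!is.null(press)) 1 - press[fit$ncomp] / sum(ys^2) else NA_real_,
    press = press,
    ssy = ssy,
    variables = colnames(X),
    scale = scale
  ), class = "plsr_fit")
  out$vip <- vip_scores(out)
  out$significant_vars <- names(out$vip)[out$vip > 1]
  out
}

#' @export
print.plsr_fit <- function(x, ...) {
  cat(sprintf("PLSR: %d component(s), %d variable(s), r2 = %.3f",
              x$ncomp, length(x$variables), x$r2))
  if (!is.na(x$q2)) cat(sprintf(", LOO q2 = %.3f", x$q2))
  cat("\n", length(x$significant_vars), " variable(s) with VIP > 1\n",
      sep = "")
  invisible(x)
}

#' Variable importance in projection (VIP)
#'
#' `VIP_j = sqrt( p * sum_a[ SSY_a * w_ja^2 ] / sum_a SSY_a )` with
#' orthonormal component weights `w_a` and `SSY_a` the response variance
#' explained by component `a`; mean squared VIP over variables is 1
#' (`sum VIP^2 = p`). Variables with VIP > 1 are conventionally called
#' significant predictors.
#'
#' @param model a `plsr_fit`.
#' @return named numeric vector of VIP scores (one per variable).
#' @export
vip_scores <- function(model) {
  W <- model$W
  ssy <- model$ssy
  wn <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  vip <- sqrt(length(model$variables) * drop(wn^2 %*% ssy) / sum(ssy))
  setNames(vip, model$variables)
}

#' Multiple linear regression with overall F test
#'
#' Ordinary least squares of the response on all columns, reporting r2,
#' adjusted r2 (`1 - (1 - r2)(n - 1)/(n - p - 1)`), and the overall F-test
#' p-value. Rank-deficient designs are an error naming the collinear
#' columns.
#'
#' @param x a `variable_matrix` or numeric matrix; requires `n > p + 1`.
#' @param y response (ignored for a `variable_matrix`).
#' @return object of class `mlr_fit`: `coefficients`, `r2`, `adj_r2`,
#'   `F`, `p`, `df`.
#' @export
fit_mlr <- function(x, y = NULL) {
  if (inherits(x, "variable_matrix")) {
    y <- x$y
    X <- x$X
  } else {
    X <- as.matrix(x)
  }
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 (n = ", n, ", p = ", p, ")")
  fit <- lm(y ~ X)
  if (any(is.na(coef(fit)))) {
    bad <- sub("^X", "", names(coef(fit))[is.na(coef(fit))])
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  structure(list(
    coefficients = setNames(coef(fit), c("(Intercept)", colnames(X))),
    r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
    F = unname(fstat[1]),
    p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    df = unname(fstat[2:3])
  ), class = "mlr_fit")
}

#' Compare explanatory-variable suites
#'
#' For each named suite (a set of provenance tags selecting columns of one
#' assembled matrix, or an explicit column-name vector), fits PLSR and,
#' where `n > p + 1`, MLR, and reports calibration r2, the chosen component
#' count, MLR adjusted r2 and p, and whether the suite improves on the
#' `"abiotic"` suite's PLSR r2. Empty suites are skipped with a warning.
#'
#' @param vm a `variable_matrix`.
#' @param suites named list; each element is a character vector of
#'   provenance tags (matched against `vm$provenance`) and/or exact column
#'   names.
#' @param ... passed to [fit_plsr()] (e.g. `scale`, `ncomp`).
#' @return data frame with one row per suite: `suite`, `n_vars`,
#'   `plsr_r2`, `plsr_q2`, `plsr_ncomp`, `n_vip_gt1`, `mlr_adj_r2`,
#'   `mlr_p`, `improves_over_abiotic`.
#' @export
compare_models <- function(vm,
                           suites = list(
                             abiotic = "abiotic",
                             abiotic_guilds = c("abiotic", "guild_sum"),
                             full = c("abiotic", "otu_gt1pct",
                                      "lineage_sum", "mag_lineage_sum",
                                      "guild_sum")),
                           ...) {
  stopifnot(inherits(vm, "variable_matrix"), length(suites) >= 2)
  rows <- lapply(names(suites), function(nm) {
    sel <- vm$provenance %in% suites[[nm]] |
      colnames(vm$X) %in% suites[[nm]]
    if (!any(sel)) {
      warning("suite '", nm, "' selects no columns; skipped")
      return(NULL)
    }
    X <- vm$X[, sel, drop = FALSE]
    pl <- fit_plsr(X, vm$y, ...)
    ml <- if (nrow(X) > ncol(X) + 1) {
      tryCatch(fit_mlr(X, vm$y), error = function(e) NULL)
    } else {
      NULL
    }
    data.frame(suite = nm, n_vars = ncol(X),
               plsr_r2 = pl$r2, plsr_q2 = pl$q2, plsr_ncomp = pl$ncomp,
               n_vip_gt1 = length(pl$significant_vars),
               mlr_adj_r2 = if (is.null(ml)) NA_real_ else ml$adj_r2,
               mlr_p = if (is.null(ml)) NA_real_ else ml$p)
  })
  out <- do.call(rbind, rows)
  base <- out$plsr_r2[out$suite == "abiotic"]
  out$improves_over_abiotic <- if (length(base) == 1) {
    out$plsr_r2 > base
  } else {
    NA
  }
  rownames(out) <- NULL
  out
}

#' Headline model statistics for a field dataset
#'
#' Recomputes, from a supplied OTU table and chemistry, the headline
#' quantities of the study design: PLSR r2 for the abiotic-only and the
#' full (abiotic + community) suites, MLR adjusted r2 for both, the number
#' of VIP > 1 variables in the full model, and the methanogen maximum and
#' ANME mean relative abundances. Both autoscaled and centered-only PLSR
#' fits are returned so the matching configuration can be identified.
#'
#' @param otu a `limnoch4_otu`.
#' @param chem matched chemistry table.
#' @param guilds,mag_map passed to [assemble_variables()].
#' @return list with one element per scaling mode (`autoscaled`,
#'   `centered`), each holding the comparison table, VIP count, and guild
#'   summaries.
#' @export
headline_statistics <- function(otu, chem, guilds = read_guild_map(),
                                    mag_map = default_mag_map()) {
  vm <- assemble_variables(otu, chem, guilds = guilds, mag_map = mag_map)
  ga <- guild_abundance(otu, guilds)
  lapply(c(autoscaled = TRUE, centered = FALSE), function(sc) {
    cmp <- compare_models(vm, scale = sc)
    list(comparison = cmp,
         n_variables_total = ncol(vm$X),
         n_vip_gt1_full = cmp$n_vip_gt1[cmp$suite == "full"],
         methanogen_max_pct = max(ga$abundance$methanogen),
         methanogen_range_pct = range(ga$abundance$methanogen),
         anme_mean_pct = mean(ga$abundance$ANME))
  })
}
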