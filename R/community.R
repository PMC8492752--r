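# OTU-table processing and community statistics: rarefaction, replicate
# averaging, Bray-Curtis (via vegan), PCoA, one-way PERMANOVA, Mantel tests,
# functional-guild relative abundances, and qPCR absolute quantification.

counts_of <- function(x) {
  if (inherits(x, "limnoch4_otu")) x$counts else as.matrix(x)
}

#' Rarefy an OTU table to a fixed library size
#'
#' Single-draw subsampling without replacement to exactly `depth` reads per
#' sample, deterministic under `seed`. Samples whose total is below `depth`
#' are dropped with a warning naming them; a sample whose total equals
#' `depth` is returned unchanged.
#'
#' @param otu a `limnoch4_otu` or a samples-by-OTUs count matrix.
#' @param depth target reads per sample (default 3000).
#' @param seed RNG seed for the draw.
#' @return same type as the input, with every retained sample summing to
#'   exactly `depth`.
#' @export
rarefy_counts <- function(otu, depth = 3000, seed = 1) {
  if (depth < 1) stop("rarefaction depth must be at least 1")
  counts <- counts_of(otu)
  totals <- rowSums(counts)
  low <- totals < depth
  if (all(low)) stop("all samples are below the rarefaction depth")
  if (any(low)) {
    warning("dropping ", sum(low), " sample(s) below depth ", depth, ": ",
            paste(rownames(counts)[low], collapse = ", "))
  }
  counts <- counts[!low, , drop = FALSE]
  out <- with_stream(seed, 5L, {
    t(apply(counts, 1, function(x) {
      if (sum(x) == depth) return(x)
      pool <- rep.int(seq_along(x), x)
      drawn <- sample(pool, depth)
      tabulate(drawn, nbins = length(x))
    }))
  })
  dimnames(out) <- dimnames(counts)
  if (inherits(otu, "limnoch4_otu")) {
    otu$counts <- out
    otu$meta <- otu$meta[otu$meta$sample %in% rownames(out), , drop = FALSE]
    otu
  } else {
    out
  }
}

#' Average technical replicate pairs
#'
#' Per-OTU arithmetic mean within each replicate group (groups of one pass
#' through unchanged); groups larger than two are an error, matching a
#' paired-replicate design.
#'
#' @param otu a `limnoch4_otu` (groups default to `meta$replicate_group`) or
#'   a count matrix plus an explicit `groups` vector.
#' @param groups replicate-group label per sample.
#' @return same type as the input, one row per group (counts may be
#'   non-integer after averaging).
#' @export
average_replicates <- function(otu, groups = NULL) {
  counts <- counts_of(otu)
  if (is.null(groups) && inherits(otu, "limnoch4_otu")) {
    groups <- otu$meta$replicate_group[match(rownames(counts),
                                             otu$meta$sample)]
  }
  if (is.null(groups)) stop("replicate groups must be supplied")
  sizes <- table(groups)
  if (any(sizes > 2)) {
    stop("replicate groups larger than 2 are not supported: ",
         paste(names(sizes)[sizes > 2], collapse = ", "))
  }
  glev <- unique(groups)
  out <- t(vapply(glev, function(g) {
    colMeans(counts[groups == g, , drop = FALSE])
  }, numeric(ncol(counts))))
  rownames(out) <- glev
  colnames(out) <- colnames(counts)
  if (inherits(otu, "limnoch4_otu")) {
    meta <- otu$meta[match(glev, otu$meta$replicate_group), , drop = FALSE]
    meta$sample <- glev
    rownames(meta) <- NULL
    otu$counts <- out
    otu$meta <- meta
    otu
  } else {
    out
  }
}

#' Bray-Curtis dissimilarity on (transformed) abundances
#'
#' Square-root transforms abundances by default, then computes Bray-Curtis
#' dissimilarity `d = sum|x - y| / sum(x + y)` between samples.
#'
#' @param otu a `limnoch4_otu` or samples-by-OTUs matrix with at least two
#'   samples and no all-zero sample.
#' @param transform `"sqrt"` (default) or `"none"`.
#' @return a `dist` object with values in `[0, 1]`.
#' @export
bray_curtis <- function(otu, transform = c("sqrt", "none")) {
  transform <- match.arg(transform)
  x <- counts_of(otu)
  if (nrow(x) < 2) stop("need at least two samples")
  if (any(rowSums(x) == 0)) stop("all-zero sample(s) present")
  if (transform == "sqrt") x <- sqrt(x)
  vegan::vegdist(x, method = "bray")
}

#' Principal coordinates analysis of a distance matrix
#'
#' Gower double-centering of `-0.5 * D^2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; negative eigenvalues are reported, not corrected. Percent
#' variation is relative to the sum of positive eigenvalues.
#'
#' @param d a `dist` or symmetric distance matrix (>= 3 samples).
#' @return list of class `limnoch4_pcoa`: `points` (samples x axes),
#'   `eigenvalues`, `pct_variation`, `negative_eigenvalues`.
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 3) stop("need at least three samples")
  A <- -0.5 * dm^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- J %*% A %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pos <- e$values > max(abs(e$values)) * 1e-10
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(pts) <- rownames(dm)
  colnames(pts) <- paste0("PCo", seq_len(ncol(pts)))
  structure(list(points = pts,
                 eigenvalues = e$values,
                 pct_variation = 100 * e$values[pos] / sum(e$values[pos]),
                 negative_eigenvalues = e$values[e$values <
                                                   -max(abs(e$values)) * 1e-10]),
            class = "limnoch4_pcoa")
}

ss_within <- function(m2, groups) {
  sum(vapply(unique(groups), function(g) {
    idx <- which(groups == g)
    sum(m2[idx, idx]) / (2 * length(idx))
  }, numeric(1)))
}

# all distinct orderings of a label multiset (small n only)
multiset_perms <- function(labels) {
  labels <- as.character(labels)
  rec <- function(lab) {
    if (length(lab) == 1) return(list(lab))
    out <- list()
    for (u in unique(lab)) {
      rest <- lab[-match(u, lab)]
      for (p in rec(rest)) out[[length(out) + 1L]] <- c(u, p)
    }
    out
  }
  rec(labels)
}

#' One-way PERMANOVA on a distance matrix
#'
#' Partitions the total sum of squared distances (total minus within-group)
#' into among- and within-group components and forms the pseudo-F statistic;
#' significance is assessed by permuting group labels. With
#' `exhaustive = TRUE` all distinct relabelings are enumerated and the
#' p-value is the exact proportion with pseudo-F at least as large as
#' observed (small n only).
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param groups group label per sample (>= 2 groups, each of size >= 2).
#' @param n_perm number of label permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @param exhaustive enumerate all distinct relabelings instead of sampling.
#' @return list of class `limnoch4_permanova`: `F`, `p`, `df`, `n_perm`,
#'   `exhaustive`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1,
                      exhaustive = FALSE) {
  m2 <- as.matrix(d)^2
  n <- nrow(m2)
  groups <- as.character(groups)
  if (length(groups) != n) stop("groups length must match the matrix")
  sizes <- table(groups)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group needs at least two members")
  k <- length(sizes)
  sst <- sum(m2) / (2 * n)
  f_of <- function(g) {
    ssw <- ss_within(m2, g)
    ((sst - ssw) / (k - 1)) / (ssw / (n - k))
  }
  f_obs <- f_of(groups)
  if (exhaustive) {
    perms <- multiset_perms(groups)
    fs <- vapply(perms, f_of, numeric(1))
    p <- mean(fs >= f_obs - 1e-12)
    n_used <- length(perms)
  } else {
    count <- with_stream(seed, 6L, {
      sum(vapply(seq_len(n_perm), function(i) {
        f_of(groups[sample.int(n)]) >= f_obs - 1e-12
      }, logical(1)))
    })
    p <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(F = f_obs, p = p, df = c(k - 1, n - k), n_perm = n_used,
                 exhaustive = exhaustive),
            class = "limnoch4_permanova")
}

#' @export
print.limnoch4_permanova <- function(x, ...) {
  cat(sprintf("One-way PERMANOVA: pseudo-F(%d, %d) = %.3f, p = %.4g (%s)\n",
              x$df[1], x$df[2], x$F, x$p,
              if (x$exhaustive) "exhaustive" else
                paste(x$n_perm, "permutations")))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Correlates the condensed upper triangles (Spearman rank correlation by
#' default) and assesses significance by permuting the rows and columns of
#' the second matrix (one-sided: permuted correlation >= observed).
#' `n_perm = "exhaustive"` enumerates all label permutations (small n).
#'
#' @param dA,dB `dist` objects or symmetric matrices over the same samples
#'   in the same order.
#' @param method correlation method (`"spearman"` default, or `"pearson"`).
#' @param n_perm number of permutations, or `"exhaustive"`.
#' @param seed RNG seed.
#' @return list with `rho`, `p`, `n_perm`, `zero_variance` flag (if either
#'   condensed vector is constant, `rho` and `p` are NA).
#' @export
mantel_test <- function(dA, dB, method = c("spearman", "pearson"),
                        n_perm = 999, seed = 1) {
  method <- match.arg(method)
  ma <- as.matrix(dA)
  mb <- as.matrix(dB)
  if (!all(dim(ma) == dim(mb))) stop("matrices differ in size")
  n <- nrow(ma)
  low <- lower.tri(ma)
  va <- ma[low]
  if (var(va) == 0 || var(mb[low]) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n_perm = 0,
                zero_variance = TRUE))
  }
  rho_of <- function(perm) cor(va, mb[perm, perm][low], method = method)
  rho_obs <- rho_of(seq_len(n))
  if (identical(n_perm, "exhaustive")) {
    perms <- multiset_perms(seq_len(n))
    rhos <- vapply(perms, function(p) rho_of(as.integer(p)), numeric(1))
    p <- mean(rhos >= rho_obs - 1e-12)
    n_used <- length(perms)
  } else {
    count <- with_stream(seed, 7L, {
      sum(vapply(seq_len(n_perm), function(i) {
        rho_of(sample.int(n)) >= rho_obs - 1e-12
      }, logical(1)))
    })
    p <- (1 + count) / (1 + n_perm)
    n_used <- n_perm
  }
  list(rho = rho_obs, p = p, n_perm = n_used, zero_variance = FALSE)
}

#' Summed relative abundances by taxonomic lineage
#'
#' Sums per-sample relative abundances (percent) of OTUs sharing the
#' taxonomy string's field at `level` (1 = domain, 2 = phylum, 3 = class,
#' ...). Lineages named in `class_override` are split one level deeper.
#'
#' @param counts samples-by-OTUs matrix.
#' @param taxonomy named character vector of semicolon-delimited lineages.
#' @param level taxonomy field to group on (default 2, phylum).
#' @param class_override lineage names to resolve at `level + 1`.
#' @return samples x lineages matrix of percent relative abundance.
#' @export
lineage_sums <- function(counts, taxonomy, level = 2,
                         class_override = character()) {
  taxonomy <- taxonomy[colnames(counts)]
  fields <- strsplit(taxonomy, ";", fixed = TRUE)
  lab <- vapply(fields, function(f) {
    top <- if (length(f) >= level) f[level] else f[length(f)]
    if (top %in% class_override && length(f) > level) f[level + 1] else top
  }, character(1))
  rel <- sweep(counts, 1, rowSums(counts), "/") * 100
  agg <- t(rowsum(t(rel), lab))
  agg[, order(colnames(agg)), drop = FALSE]
}

#' Read a functional-guild map
#'
#' Guild maps are YAML: guild name to a list of taxonomy substring patterns.
#' Matching is case-insensitive substring on the full lineage string, and a
#' taxon is assigned to the first guild (in file order) that matches, so
#' narrower guilds (e.g. ANME, nested inside Methanosarcinales) must precede
#' broader ones. The default map shipped with the package covers known
#' methanogenic orders, ANME clades, aerobic methanotroph families, and
#' Syntrophaceae, and is meant to be edited.
#'
#' @param path YAML file; default is the map shipped in `extdata`.
#' @return named list of character pattern vectors, in file order.
#' @export
read_guild_map <- function(path = system.file("extdata", "guilds.yml",
                                              package = "limnoch4")) {
  gm <- yaml::read_yaml(path)
  if (any(lengths(gm) == 0)) stop("guild with no patterns in ", path)
  lapply(gm, as.character)
}

match_guilds <- function(taxonomy, guilds) {
  tl <- tolower(taxonomy)
  assigned <- rep(NA_character_, length(taxonomy))
  for (g in names(guilds)) {
    pat <- tolower(guilds[[g]])
    hit <- Reduce(`|`, lapply(pat, function(p) grepl(p, tl, fixed = TRUE)))
    assigned[is.na(assigned) & hit] <- g
  }
  setNames(assigned, names(taxonomy))
}

#' Per-sample functional-guild relative abundances with group tests
#'
#' Sums the relative abundance (percent of reads) of all OTUs matching each
#' guild's taxonomy patterns, then compares edges to middles per guild by a
#' two-tailed Student's t-test and a one-way ANOVA (for two groups the two
#' agree, F = t^2; both are reported for parity with mixed reporting
#' conventions).
#'
#' @param otu a `limnoch4_otu` (zone labels taken from `meta`) or a count
#'   matrix (no tests possible without metadata).
#' @param guilds guild map from [read_guild_map()].
#' @return list with `abundance` (sample metadata plus one percent column
#'   per guild) and `tests` (guild, mean_edge, mean_middle, t_p, anova_p).
#'   Guilds matching no OTU get zero abundances and a warning.
#' @export
guild_abundance <- function(otu, guilds = read_guild_map()) {
  counts <- counts_of(otu)
  taxonomy <- if (inherits(otu, "limnoch4_otu")) otu$taxonomy else NULL
  if (is.null(taxonomy)) stop("guild_abundance needs taxonomy strings")
  assigned <- match_guilds(taxonomy[colnames(counts)], guilds)
  rel <- sweep(counts, 1, rowSums(counts), "/") * 100
  ab <- vapply(names(guilds), function(g) {
    idx <- which(assigned == g)
    if (length(idx) == 0) {
      warning("guild '", g, "' matches no OTU; abundances set to 0")
      return(rep(0, nrow(rel)))
    }
    rowSums(rel[, idx, drop = FALSE])
  }, numeric(nrow(rel)))
  meta <- otu$meta[match(rownames(counts), otu$meta$sample), , drop = FALSE]
  abundance <- cbind(meta, as.data.frame(ab))
  rownames(abundance) <- NULL
  tests <- NULL
  if ("zone" %in% names(meta) && length(unique(meta$zone)) == 2) {
    tests <- do.call(rbind, lapply(names(guilds), function(g) {
      x <- abundance[[g]]
      z <- abundance$zone
      tp <- ap <- NA_real_
      if (var(x) > 0) {
        tp <- tryCatch(t.test(x ~ z)$p.value, error = function(e) NA_real_)
        ap <- summary(aov(x ~ z))[[1]][["Pr(>F)"]][1]
      }
      data.frame(guild = g,
                 mean_edge = mean(x[z == "edge"]),
                 mean_middle = mean(x[z == "middle"]),
                 t_p = tp, anova_p = ap)
    }))
    rownames(tests) <- NULL
  }
  list(abundance = abundance, tests = tests)
}

#' qPCR standard description
#'
#' Defaults describe an E. coli genomic DNA standard: genome 4,686,137 bp
#' carrying 7 16S rRNA gene copies, a 20 ng/uL stock diluted 1e-2..1e-6, and
#' a mean molar mass of 650 g/mol per base pair.
#'
#' @param genome_size_bp,gene_copies_per_genome,stock_ng_per_uL,dilutions,mean_bp_mass
#'   see description; all must be positive.
#' @return list of class `qpcr_standard`.
#' @export
qpcr_standard <- function(genome_size_bp = 4686137,
                          gene_copies_per_genome = 7,
                          stock_ng_per_uL = 20,
                          dilutions = 10^-(2:6),
                          mean_bp_mass = 650) {
  std <- list(genome_size_bp = genome_size_bp,
              gene_copies_per_genome = gene_copies_per_genome,
              stock_ng_per_uL = stock_ng_per_uL,
              dilutions = dilutions, mean_bp_mass = mean_bp_mass)
  if (any(unlist(std) <= 0)) stop("all standard fields must be positive")
  class(std) <- "qpcr_standard"
  std
}

AVOGADRO <- 6.02214076e23

# 16S gene copies per uL in each standard dilution
standard_copies_per_uL <- function(std) {
  genome_mass_g <- std$genome_size_bp * std$mean_bp_mass / AVOGADRO
  std$dilutions * std$stock_ng_per_uL * 1e-9 / genome_mass_g *
    std$gene_copies_per_genome
}

#' Absolute 16S abundance from qPCR Ct values
#'
#' Fits the standard curve (OLS of Ct on log10 gene copies per uL, copies
#' computed from the stock mass, genome size, and per-genome gene count),
#' interpolates sample Cts, and converts to copies per g wet sediment via
#' the template dilution and the extraction normalization (mass extracted
#' into the elution volume). Sample Cts outside the standard range are
#' flagged as extrapolated.
#'
#' @param samples data frame with `sample`, `Ct`, `dilution` (template
#'   dilution factor, e.g. 100 for 1/100), or a `limnoch4_qpcr_plate` (in
#'   which case `standards`, `elution_uL`, and `mass_g` are taken from it).
#' @param standards data frame with `dilution` and `Ct` for the standard
#'   series (>= 3 points spanning >= 2 decades).
#' @param standard a [qpcr_standard()].
#' @param elution_uL DNA elution volume (uL).
#' @param mass_g wet sediment mass extracted (g).
#' @return list with `samples` (input plus `copies_per_uL`, `copies_per_g`,
#'   `extrapolated`), `curve` (slope, intercept, r2, efficiency).
#' @export
quantify_qpcr <- function(samples, standards = NULL,
                          standard = qpcr_standard(),
                          elution_uL = 100, mass_g = 0.25) {
  if (inherits(samples, "limnoch4_qpcr_plate")) {
    plate <- samples
    samples <- plate$samples
    standards <- standards %||% plate$standards
    elution_uL <- plate$elution_uL
    mass_g <- plate$mass_g
  }
  if (is.null(standards)) stop("standard series required")
  if (nrow(standards) < 3) stop("need at least 3 standard points")
  copies <- standard_copies_per_uL(
    qpcr_standard(standard$genome_size_bp, standard$gene_copies_per_genome,
                  standard$stock_ng_per_uL, standards$dilution,
                  standard$mean_bp_mass))
  if (diff(range(log10(copies))) < 2) {
    stop("standard series must span at least two decades")
  }
  fit <- lm(standards$Ct ~ log10(copies))
  a <- unname(coef(fit)[1])
  b <- unname(coef(fit)[2])
  log_copies <- (samples$Ct - a) / b
  out <- samples
  out$copies_per_uL <- 10^log_copies
  out$copies_per_g <- out$copies_per_uL * samples$dilution *
    elution_uL / mass_g
  out$extrapolated <- samples$Ct < min(standards$Ct) |
    samples$Ct > max(standards$Ct)
  list(samples = out,
       curve = list(slope = b, intercept = a,
                    r2 = summary(fit)$r.squared,
                    efficiency = 10^(-1 / b) - 1))
}

#' Absolute-abundance proxy for a guild
#'
#' Multiplies per-sample guild relative abundance by the qPCR total 16S
#' copies per g, giving a per-guild copies-per-gram proxy, and repeats the
#' edge-versus-middle test on the proxy. Because total copies decline
#' steeply with depth while guild enrichment is a zone effect, proxy
#' contrasts are typically attenuated relative to relative-abundance
#' contrasts.
#'
#' @param relabund the `abundance` data frame from [guild_abundance()].
#' @param qpcr data frame with `sample` and `copies_per_g` (e.g.
#'   `quantify_qpcr(...)$samples`).
#' @param guild name of the guild column to use (default `"methanogen"`).
#' @return list with `proxy` (sample, zone, relabund_pct, copies_per_g,
#'   proxy_copies_per_g) and `tests` (t_p, anova_p on the proxy), with
#'   unmatched samples dropped (warning).
#' @export
absolute_guild_proxy <- function(relabund, qpcr, guild = "methanogen") {
  if (!guild %in% names(relabund)) stop("no column '", guild, "'")
  m <- merge(relabund[, c("sample", "zone", guild)],
             qpcr[, c("sample", "copies_per_g")], by = "sample")
  dropped <- setdiff(union(relabund$sample, qpcr$sample), m$sample)
  if (length(dropped)) {
    warning("dropping unmatched sample(s): ",
            paste(dropped, collapse = ", "))
  }
  m$proxy_copies_per_g <- m[[guild]] / 100 * m$copies_per_g
  tests <- NULL
  if (length(unique(m$zone)) == 2 && var(m$proxy_copies_per_g) > 0 &&
      all(table(m$zone) >= 2)) {
    tests <- data.frame(
      t_p = t.test(proxy_copies_per_g ~ zone, data = m)$p.value,
      anova_p = summary(aov(proxy_copies_per_g ~ zone,
                            data = m))[[1]][["Pr(>F)"]][1])
  }
  list(proxy = m, tests = tests)
}
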