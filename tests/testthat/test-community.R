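toy_otu <- function(counts, tax = NULL, meta = NULL) {
  if (is.null(tax)) {
    tax <- setNames(paste0("Bacteria;Phy", seq_len(ncol(counts))),
                    colnames(counts))
  }
  structure(list(counts = counts, taxonomy = tax, meta = meta),
            class = "limnoch4_otu")
}

test_that("rarefaction is exact at the threshold and drops shallow samples", {
  m <- rbind(a = c(1000, 1000, 1000), b = c(2999, 0, 0),
             c = c(1500, 1500, 100))
  colnames(m) <- paste0("OTU", 1:3)
  expect_warning(r <- rarefy_counts(m, depth = 3000, seed = 1), "\\bb\\b")
  expect_identical(rownames(r), c("a", "c"))
  expect_equal(unname(r["a", ]), c(1000, 1000, 1000))
  expect_true(all(rowSums(r) == 3000))
  expect_error(rarefy_counts(m[2, , drop = FALSE], 3000), "below")
  expect_error(rarefy_counts(m, 0), "at least 1")
  # deterministic under seed, different across seeds
  expect_identical(rarefy_counts(m, 2000, seed = 3),
                   rarefy_counts(m, 2000, seed = 3))
})

test_that("rarefied counts match the binomial expectation depth * p_i", {
  x <- c(30, 20, 10)  # total 60
  m <- matrix(x, nrow = 1, dimnames = list("s", paste0("OTU", 1:3)))
  depth <- 30
  draws <- vapply(1:200, function(s) rarefy_counts(m, depth, seed = s)[1, ],
                  numeric(3))
  expected <- depth * x / sum(x)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - expected) <= 3 * se + 1e-9))
})

test_that("replicate averaging means pairs and rejects larger groups", {
  m <- rbind(r1 = c(10, 0), r2 = c(20, 4), s = c(5, 5))
  colnames(m) <- c("A", "B")
  avg <- average_replicates(m, groups = c("g1", "g1", "g2"))
  expect_equal(unname(avg["g1", ]), c(15, 2))
  expect_equal(unname(avg["g2", ]), c(5, 5))
  ident <- average_replicates(rbind(m[1, ], m[1, ]), groups = c("g", "g"))
  expect_equal(unname(ident[1, ]), unname(m[1, ]))
  expect_error(average_replicates(m, groups = rep("g", 3)), "larger than 2")
})

test_that("Bray-Curtis honors the hand-computed values", {
  m <- rbind(x = c(1, 0), y = c(0, 1))
  expect_equal(as.numeric(bray_curtis(m)), 1)
  m2 <- rbind(x = c(4, 4), y = c(1, 1))
  expect_equal(as.numeric(bray_curtis(m2)), 1 / 3)          # sqrt transform
  expect_equal(as.numeric(bray_curtis(m2, transform = "none")), 3 / 5)
  expect_equal(as.numeric(bray_curtis(rbind(a = c(3, 7), b = c(3, 7)))), 0)
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(1, 1))), "all-zero")
  d <- bray_curtis(generate_otu_table(small_config())$counts)
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA recovers planar geometry and its eigenvalue identities", {
  # collinear points: a single positive eigenvalue
  line <- matrix(c(0, 1, 2, 3.5), ncol = 1)
  p1 <- pcoa(dist(line))
  expect_identical(ncol(p1$points), 1L)
  expect_equal(sum(p1$eigenvalues > 1e-8), 1)

  # 2-D configuration recovered up to rotation/reflection
  set.seed(5)
  xy <- matrix(rnorm(20), ncol = 2)
  p2 <- pcoa(dist(xy))
  expect_lt(procrustes_error(xy, p2$points[, 1:2]), 1e-8)

  # eigenvalue sum equals the trace of the centered Gower matrix,
  # and coordinates agree with classical MDS
  d <- bray_curtis(generate_otu_table(small_config(seed = 2))$counts)
  p3 <- pcoa(d)
  dm <- as.matrix(d)
  J <- diag(nrow(dm)) - 1 / nrow(dm)
  B <- J %*% (-0.5 * dm^2) %*% J
  expect_equal(sum(p3$eigenvalues), sum(diag(B)), tolerance = 1e-8)
  cm <- cmdscale(d, k = 2)
  expect_lt(procrustes_error(cm, p3$points[, 1:2]), 1e-6)
  expect_error(pcoa(dist(matrix(1:2, ncol = 1))), "three")
})

test_that("PERMANOVA matches vegan and exhaustive enumeration", {
  set.seed(8)
  m <- matrix(rpois(6 * 12, 20), nrow = 6,
              dimnames = list(paste0("s", 1:6), NULL))
  groups <- rep(c("A", "B"), each = 3)
  d <- bray_curtis(m)

  ours <- permanova(d, groups, n_perm = 999, seed = 1)
  df <- data.frame(groups = groups)
  veg <- vegan::adonis2(d ~ groups, data = df, permutations = 999)
  expect_equal(ours$F, veg$F[1], tolerance = 1e-10)

  # brute-force oracle: all 20 distinct relabelings, F via vegan
  combos <- combn(6, 3)
  fs <- apply(combos, 2, function(idx) {
    g <- rep("B", 6)
    g[idx] <- "A"
    vegan::adonis2(d ~ g, data = data.frame(g = g),
                   permutations = 2)$F[1]
  })
  p_oracle <- mean(fs >= ours$F - 1e-12)
  exh <- permanova(d, groups, exhaustive = TRUE)
  expect_equal(exh$p, p_oracle, tolerance = 1e-12)
  expect_identical(exh$n_perm, 20L)

  expect_error(permanova(d, rep("A", 6)), "two groups")
  expect_error(permanova(d, c("A", rep("B", 5))), "two members")
})

test_that("Mantel statistics match vegan and exhaustive enumeration", {
  set.seed(3)
  a <- dist(matrix(rnorm(10), ncol = 2))
  expect_equal(mantel_test(a, a, n_perm = 99)$rho, 1)
  b <- as.matrix(a)
  rev_b <- max(b) - b
  diag(rev_b) <- 0
  expect_equal(mantel_test(a, as.dist(rev_b), n_perm = 99)$rho, -1)

  other <- dist(matrix(rnorm(10), ncol = 2))
  ours <- mantel_test(a, other, n_perm = 999, seed = 4)
  veg <- vegan::mantel(a, other, method = "spearman", permutations = 99)
  expect_equal(ours$rho, veg$statistic, tolerance = 1e-10)

  exh <- mantel_test(a, other, n_perm = "exhaustive")
  expect_identical(exh$n_perm, 120L)
  # sampled p agrees with the exhaustive p within binomial error
  expect_lt(abs(ours$p - exh$p),
            3 * sqrt(exh$p * (1 - exh$p) / 999) + 2 / 999)

  z <- as.dist(matrix(0, 5, 5))
  expect_true(mantel_test(z, a)$zero_variance)
})

test_that("guild abundances sum matching OTUs and report paired tests", {
  counts <- rbind(e1 = c(30, 2970, 0), e2 = c(25, 2975, 0),
                  m1 = c(70, 2925, 5), m2 = c(65, 2930, 5))
  colnames(counts) <- c("OTU_1", "OTU_2", "OTU_3")
  tax <- c(OTU_1 = "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;X;Y",
           OTU_2 = "Bacteria;Chloroflexi;Anaerolineae;Z;Z;Z",
           OTU_3 = "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;ANME-2d;ANME-2d")
  meta <- data.frame(sample = rownames(counts),
                     zone = c("edge", "edge", "middle", "middle"))
  otu <- toy_otu(counts, tax, meta)
  ga <- guild_abundance(otu, read_guild_map())
  expect_equal(ga$abundance$methanogen[1], 1)  # 30 of 3000 reads
  # ANME resolves before the methanogen patterns despite Methanosarcinales
  expect_equal(ga$abundance$ANME, c(0, 0, 5, 5) / 3000 * 100)
  tot <- rowSums(sweep(counts, 1, rowSums(counts), "/") * 100)
  expect_equal(unname(tot), rep(100, 4), tolerance = 1e-9)
  # two-group ANOVA F equals t^2: identical p-values
  mg <- ga$tests[ga$tests$guild == "methanogen", ]
  tt <- t.test(ga$abundance$methanogen ~ ga$abundance$zone,
               var.equal = TRUE)$p.value
  expect_equal(mg$anova_p, tt, tolerance = 1e-10)
  expect_warning(
    guild_abundance(otu, list(methanogen = "Methanomicrobiales",
                              missing_guild = "Nothing_matches")),
    "missing_guild")
})

test_that("qPCR quantification inverts the standard curve", {
  std <- qpcr_standard()
  # 1e-2 dilution of 20 ng/uL with a 5.06 fg genome and 7 gene copies
  copies <- limnoch4:::standard_copies_per_uL(std)
  expect_equal(copies[1], 2.77e5, tolerance = 0.005)
  expect_equal(copies[1] / copies[2], 10, tolerance = 1e-9)

  cfg <- small_config(qpcr_ct_sd = 0)
  plate <- generate_qpcr_plate(cfg)
  q <- quantify_qpcr(plate)
  expect_equal(q$curve$r2, 1, tolerance = 1e-9)
  expect_equal(q$curve$efficiency, 1, tolerance = 1e-6)
  expect_equal(q$samples$copies_per_g, plate$truth$copies_per_g,
               tolerance = 1e-6)
  expect_error(quantify_qpcr(plate$samples, plate$standards[1:2, ]),
               "3 standard")
  # a Ct far outside the standards is flagged as extrapolated
  hot <- plate$samples[1, ]
  hot$Ct <- max(plate$standards$Ct) + 5
  qh <- quantify_qpcr(hot, plate$standards)
  expect_true(qh$samples$extrapolated)
})

test_that("absolute guild proxies multiply through and attenuate zone contrasts", {
  relab <- data.frame(sample = c("s1", "s2"), zone = c("edge", "middle"),
                      methanogen = c(1, 2))
  qpcr <- data.frame(sample = c("s1", "s2", "s3"),
                     copies_per_g = c(1e9, 1e9, 1e9))
  expect_warning(pr <- absolute_guild_proxy(relab, qpcr), "s3")
  expect_equal(pr$proxy$proxy_copies_per_g, c(1e7, 2e7))

  # constant qPCR totals preserve the relative-abundance test p-value
  cfg <- small_config(seed = 13)
  otu <- generate_otu_table(cfg)
  ga <- guild_abundance(otu, read_guild_map())
  const <- data.frame(sample = ga$abundance$sample, copies_per_g = 1e9)
  pr2 <- absolute_guild_proxy(ga$abundance, const)
  mg <- ga$tests[ga$tests$guild == "methanogen", ]
  expect_equal(pr2$tests$t_p, mg$t_p, tolerance = 1e-9)

  # steep depth decay in totals attenuates the zone contrast
  plate <- generate_qpcr_plate(cfg)
  qp <- quantify_qpcr(plate)
  pr3 <- absolute_guild_proxy(ga$abundance, qp$samples)
  expect_gt(pr3$tests$t_p, mg$t_p)
})
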