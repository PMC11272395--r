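test_that("intensity filter discards probes at or above 50% below-background", {
  panel <- data.frame(
    probe_id = rep(c("a", "b", "c"), each = 10),
    above_background = c(
      rep(TRUE, 10), # 0% below: retained
      rep(c(TRUE, FALSE), 5), # exactly 50% below: discarded
      c(rep(FALSE, 4), rep(TRUE, 6)) # 40% below: retained
    )
  )
  expect_identical(filter_probes_by_intensity(panel), c("a", "c"))
  expect_error(
    filter_probes_by_intensity(data.frame(probe_id = "a", above_background = NA)),
    "defined"
  )
})

test_that("intensity filter matches a brute-force recount on random panels", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(50:200, 1)
    panel <- data.frame(
      probe_id = sample(sprintf("p%02d", 1:12), n, replace = TRUE),
      above_background = sample(c(TRUE, FALSE), n, replace = TRUE)
    )
    brute <- character(0)
    for (p in sort(unique(panel$probe_id))) {
      flags <- panel$above_background[panel$probe_id == p]
      if (sum(!flags) / length(flags) < 0.5) brute <- c(brute, p)
    }
    expect_identical(filter_probes_by_intensity(panel), brute)
  }
})

test_that("differential stability: identical, reversed and brute-force cases", {
  regions <- letters[1:6]
  ident <- make_panel(c("d1", "d2"), "g1_p01", regions,
    expr_fun = function(d, p, r) match(r, regions)
  )
  expect_equal(differential_stability(ident, "g1_p01"), 1)
  rev_panel <- make_panel(c("d1", "d2"), "g1_p01", regions,
    expr_fun = function(d, p, r) {
      if (d == "d1") match(r, regions) else 7 - match(r, regions)
    }
  )
  expect_equal(differential_stability(rev_panel, "g1_p01"), -1)
  # 3 donors, random profiles: mean of the three pairwise Spearman rhos
  set.seed(77)
  vals <- matrix(rnorm(18), 3, 6, dimnames = list(c("d1", "d2", "d3"), regions))
  rand <- make_panel(c("d1", "d2", "d3"), "g1_p01", regions,
    expr_fun = function(d, p, r) vals[d, r]
  )
  expected <- mean(c(
    cor(vals[1, ], vals[2, ], method = "spearman"),
    cor(vals[1, ], vals[3, ], method = "spearman"),
    cor(vals[2, ], vals[3, ], method = "spearman")
  ))
  expect_equal(differential_stability(rand, "g1_p01"), expected)
})

test_that("differential stability errors and warnings", {
  one_donor <- make_panel("d1", "g1_p01", letters[1:4], function(d, p, r) 1)
  expect_error(differential_stability(one_donor, "g1_p01"), "fewer than 2 donors")
  expect_error(differential_stability(one_donor, "nope"), "zero samples")
  const <- make_panel(c("d1", "d2"), "g1_p01", letters[1:4],
    expr_fun = function(d, p, r) if (d == "d1") 5 else match(r, letters)
  )
  expect_error(
    expect_warning(differential_stability(const, "g1_p01"), "constant"),
    "no valid donor pairs"
  )
})

test_that("differential stability is invariant under donor relabeling and monotone maps", {
  set.seed(3)
  vals <- matrix(rnorm(24), 3, 8, dimnames = list(paste0("d", 1:3), letters[1:8]))
  base <- make_panel(paste0("d", 1:3), "g1_p01", letters[1:8],
    expr_fun = function(d, p, r) vals[d, r]
  )
  ds0 <- differential_stability(base, "g1_p01")
  relab <- base
  relab$donor_id <- c(d1 = "dZ", d2 = "dA", d3 = "dM")[relab$donor_id]
  expect_equal(differential_stability(relab, "g1_p01"), ds0)
  mono <- base
  sel <- mono$donor_id == "d2"
  mono$expression[sel] <- exp(3 * mono$expression[sel]) + 10
  expect_equal(differential_stability(mono, "g1_p01"), ds0)
})

test_that("probe selection takes the stability argmax with lexicographic ties", {
  regions <- letters[1:6]
  # p01 perfectly stable, p02 unstable
  panel <- make_panel(c("d1", "d2"), c("g1_p01", "g1_p02"), regions,
    expr_fun = function(d, p, r) {
      if (p == "g1_p01") {
        match(r, regions)
      } else if (d == "d1") {
        match(r, regions)
      } else {
        c(3, 1, 6, 2, 5, 4)[match(r, regions)]
      }
    },
    gene_of = c(g1_p01 = "g1", g1_p02 = "g1")
  )
  expect_identical(select_probe_per_gene(panel), c(g1 = "g1_p01"))
  # exact tie (identical profiles): lexicographically smallest probe id wins
  tie <- make_panel(c("d1", "d2"), c("g1_pB", "g1_pA"), regions,
    expr_fun = function(d, p, r) match(r, regions),
    gene_of = c(g1_pB = "g1", g1_pA = "g1")
  )
  expect_identical(select_probe_per_gene(tie), c(g1 = "g1_pA"))
  # single-probe genes are selected trivially
  single <- make_panel(c("d1", "d2"), "g2_p01", regions, function(d, p, r) 1)
  single$above_background <- TRUE
  expect_identical(select_probe_per_gene(single), c(g2 = "g2_p01"))
  # genes whose probes all fail the intensity filter are dropped with a message
  dark <- make_panel(c("d1", "d2"), "g3_p01", regions, function(d, p, r) 1,
    above_background = FALSE
  )
  expect_message(out <- select_probe_per_gene(dark), "dropped")
  expect_length(out, 0L)
})

test_that("sample assignment honors the 2 mm threshold and the hemisphere constraint", {
  centroids <- data.frame(
    region_id = c("lh_a", "rh_a"), hemisphere = c("L", "R"),
    x_mm = c(-40, 40), y_mm = 0, z_mm = 0
  )
  samples <- data.frame(
    sample_id = c("near", "far", "wrong_side"),
    hemisphere = c("L", "L", "L"),
    x_mm = c(-40.5, -42.5, 39.9), y_mm = 0, z_mm = 0
  )
  res <- suppressMessages(assign_samples_to_regions(samples, centroids))
  expect_identical(res$region_id[res$sample_id == "near"], "lh_a")
  expect_true(is.na(res$region_id[res$sample_id == "far"])) # 2.5 mm > 2 mm
  # nearest centroid is 0.1 mm away but in the other hemisphere: discarded
  expect_true(is.na(res$region_id[res$sample_id == "wrong_side"]))
  # same-hemisphere centroid at 1.9 mm beats an opposite one at 0.1 mm
  both <- data.frame(
    sample_id = "s", hemisphere = "L",
    x_mm = 38.1, y_mm = 0, z_mm = 0
  )
  cent2 <- rbind(centroids, data.frame(
    region_id = "lh_b", hemisphere = "L", x_mm = 40, y_mm = 0, z_mm = 0
  ))
  expect_identical(assign_samples_to_regions(both, cent2)$region_id, "lh_b")
  expect_error(
    assign_samples_to_regions(
      data.frame(sample_id = "s", hemisphere = NA, x_mm = 0, y_mm = 0, z_mm = 0),
      centroids
    ),
    "hemisphere"
  )
})

test_that("robust sigmoid normalization matches the printed formulas", {
  x <- c(1, 2, 3, 4, 100)
  # direct evaluation: median 3, Q75 - Q25 = 4 - 2 = 2 (type-7), /1.349
  xn <- 1 / (1 + exp(-(x - 3) / (2 / 1.349)))
  expected <- (xn - min(xn)) / (max(xn) - min(xn))
  expect_equal(robust_sigmoid_normalize(x), expected)
  # the raw-IQR convention is available behind the switch
  xn_raw <- 1 / (1 + exp(-(x - 3) / 2))
  expect_equal(
    robust_sigmoid_normalize(x, iqr_scale = "raw"),
    (xn_raw - min(xn_raw)) / (max(xn_raw) - min(xn_raw))
  )
  # the median maps to 0.5 before rescaling
  expect_equal(robust_sigmoid_normalize(x, rescale = FALSE)[3], 0.5)
  # endpoints attained after rescale
  out <- robust_sigmoid_normalize(x)
  expect_equal(range(out), c(0, 1))
  expect_true(all(diff(out) > 0)) # strictly monotone
})

test_that("robust sigmoid is invariant under positive affine transforms", {
  set.seed(5)
  for (i in 1:20) {
    x <- rnorm(15)
    a <- runif(1, 0.1, 10)
    b <- runif(1, -50, 50)
    expect_equal(
      robust_sigmoid_normalize(a * x + b),
      robust_sigmoid_normalize(x),
      tolerance = 1e-10
    )
  }
  expect_warning(out <- robust_sigmoid_normalize(rep(2, 5)), "interquartile")
  expect_identical(out, rep(0.5, 5))
})

test_that("expression matrix: unit interval, donor identity and row-order invariance", {
  regions <- dk_labels()[1:8]
  set.seed(21)
  vals <- matrix(runif(8 * 3, 5, 50), 8, 3)
  probes <- c("g1_p01", "g2_p01", "g3_p01")
  one <- make_panel("d1", probes, regions,
    expr_fun = function(d, p, r) vals[match(r, regions), match(p, probes)]
  )
  m1 <- build_expression_matrix(one)
  expect_true(all(m1 >= 0 & m1 <= 1))
  expect_equal(sort(colnames(m1)), c("g1", "g2", "g3"))
  # each gene column attains 0 and 1 (single donor: averaging is identity)
  expect_true(all(apply(m1, 2, min) == 0))
  expect_true(all(apply(m1, 2, max) == 1))
  # a second donor with identical raw values changes nothing
  two <- rbind(one, transform(make_panel("d2", probes, regions,
    expr_fun = function(d, p, r) vals[match(r, regions), match(p, probes)]
  )))
  m2 <- build_expression_matrix(two)
  expect_equal(m2, m1, ignore_attr = TRUE)
  # input row order is irrelevant
  shuf <- two[sample(nrow(two)), ]
  expect_equal(build_expression_matrix(shuf), m2, ignore_attr = TRUE)
})

test_that("planted gene-map correlations survive the full reduction", {
  map <- setNames(runif(68, 1.2, 1.8), dk_labels())
  des <- probe_panel_design(
    genes = c("GABRG2", "PDYN"), probes_per_gene = 2,
    planted_rho = c(-0.45, 0.5), seed = 17
  )
  panel <- gen_probe_panel(des, exponent_map = map)
  expr <- build_expression_matrix(panel)
  res <- gene_map_correlation(map, expr)
  expect_lt(abs(res$rho[res$unit == "GABRG2"] - (-0.45)), 0.15)
  expect_lt(abs(res$rho[res$unit == "PDYN"] - 0.5), 0.15)
})

test_that("assignment-driven reduction matches the panel's own region labels", {
  regions <- dk_labels()[1:8]
  des <- probe_panel_design(
    n_donors = 2, regions = regions, genes = c("SCN1A", "KCNQ2"),
    probes_per_gene = 1, seed = 13
  )
  panel <- gen_probe_panel(des, exponent_map = 1:8)
  assigned <- assign_samples_to_regions(
    unique(panel[, c("sample_id", "hemisphere", "x_mm", "y_mm", "z_mm")]),
    dk_centroids(regions)
  )
  # jitter is < 1 mm, so proximity assignment recovers the true regions
  truth <- unique(panel[, c("sample_id", "region_id")])
  expect_identical(
    assigned$region_id[match(truth$sample_id, assigned$sample_id)],
    truth$region_id
  )
  m_a <- build_expression_matrix(panel, assignments = assigned)
  m_b <- build_expression_matrix(panel)
  expect_equal(m_a, m_b, ignore_attr = TRUE)
})
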