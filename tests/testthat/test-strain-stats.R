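mkFields <- function(values) {
  # values: named list strain -> experiment -> numeric field metrics
  rows <- list()
  for (s in names(values)) {
    for (e in names(values[[s]])) {
      v <- values[[s]][[e]]
      rows[[length(rows) + 1L]] <- data.frame(
        strain = s, experiment_id = e,
        field_id = paste0("F", seq_along(v)), n_cells = 100,
        mean_ld_per_cell = v, pct_cells_supersized = v)
    }
  }
  do.call(rbind, rows)
}

test_that("experiment tables average fields and demand a complete design", {
  fields <- mkFields(list(wt = list(E1 = c(2, 3, 4), E2 = c(5, 5, 5)),
                          mut = list(E1 = 7, E2 = c(1, 3))))
  tab <- buildExperimentTable(fields, "mean_ld_per_cell")
  expect_equal(nrow(tab), 4)
  expect_equal(tab$value[tab$strain == "wt" & tab$experiment_id == "E1"], 3)
  expect_equal(tab$value[tab$strain == "mut" & tab$experiment_id == "E1"], 7)
  expect_equal(tab$value[tab$strain == "mut" & tab$experiment_id == "E2"], 2)

  incomplete <- fields[!(fields$strain == "mut" & fields$experiment_id == "E2"), ]
  expect_error(buildExperimentTable(incomplete, "mean_ld_per_cell"),
               "missing")
  expect_error(buildExperimentTable(fields, "nope"), "not found")

  # 2 strains x 3 experiments x 3 fields -> 6 rows
  f2 <- mkFields(list(a = list(E1 = 1:3, E2 = 4:6, E3 = 7:9),
                      b = list(E1 = 2:4, E2 = 5:7, E3 = 8:10)))
  expect_equal(nrow(buildExperimentTable(f2, "mean_ld_per_cell")), 6)
})

test_that("the linked ANOVA matches the definitional sums of squares", {
  set.seed(7)
  for (i in 1:5) {
    tab <- expand.grid(strain = paste0("S", 1:3),
                       experiment_id = paste0("E", 1:4),
                       stringsAsFactors = FALSE)
    tab$value <- rnorm(12, mean = rep(c(1, 2, 3), 4), sd = 1)
    an <- linkedAnova(tab)
    or <- rcbdOracle(tab$value, tab$strain, tab$experiment_id)
    expect_equal(an$ssStrain, or$ssStrain, tolerance = 1e-10)
    expect_equal(an$ssBlock, or$ssBlock, tolerance = 1e-10)
    expect_equal(an$ssResidual, or$ssResidual, tolerance = 1e-10)
    expect_equal(an$F, or$F, tolerance = 1e-10)
    expect_equal(an$pValue, or$p, tolerance = 1e-10)
    # decomposition: SS_total = SS_strain + SS_block + SS_res
    expect_equal(an$ssStrain + an$ssBlock + an$ssResidual, or$ssTotal,
                 tolerance = 1e-10)
    expect_identical(c(an$dfStrain, an$dfBlock, an$dfResidual),
                     c(2L, 3L, 6L))
  }
})

test_that("block-only structure gives F = 0 and block shifts change SS_block only", {
  tab <- expand.grid(strain = paste0("S", 1:3),
                     experiment_id = paste0("E", 1:3),
                     stringsAsFactors = FALSE)
  # block effects plus residuals balanced to zero per strain and per block:
  # strain means are all equal, so SS_strain and F are exactly 0
  eps <- matrix(c(1, -1, 0, -1, 0, 1, 0, 1, -1), 3, 3)
  tab$value <- rep(c(10, 20, 30), each = 3) + as.vector(eps)
  an <- linkedAnova(tab)
  expect_equal(an$ssStrain, 0, tolerance = 1e-10)
  expect_equal(an$F, 0, tolerance = 1e-10)
  expect_gt(an$ssResidual, 0)

  set.seed(1)
  tab$value <- rnorm(9)
  a1 <- linkedAnova(tab)
  tab2 <- tab
  tab2$value[tab2$experiment_id == "E2"] <-
    tab2$value[tab2$experiment_id == "E2"] + 5
  a2 <- linkedAnova(tab2)
  expect_equal(a1$ssStrain, a2$ssStrain, tolerance = 1e-10)
  expect_equal(a1$ssResidual, a2$ssResidual, tolerance = 1e-10)
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_gt(a2$ssBlock, a1$ssBlock)

  expect_error(linkedAnova(tab[tab$strain != "S1", ][1:5, ]), "one value")
})

test_that("step-down Sidak adjustment follows its closed form", {
  # m = 1: adjustment is the identity
  tab <- expand.grid(strain = c("A", "B"), experiment_id = paste0("E", 1:4),
                     stringsAsFactors = FALSE)
  set.seed(2)
  tab$value <- rnorm(8)
  an <- linkedAnova(tab)
  pw <- holmSidak(list(c("A", "B")), tab, an)
  expect_equal(pw$p_adjusted, pw$p_raw, tolerance = 1e-12)

  # m = 2 closed form on raw p (0.01, 0.04): (1 - 0.99^2, 0.04)
  adj <- ldscope:::adjustStepDown(c(0.01, 0.04), "sidak")
  expect_equal(adj, c(1 - 0.99^2, 0.04), tolerance = 1e-12)
  # raw p of 1 stays 1
  expect_equal(ldscope:::adjustStepDown(c(0.3, 1), "sidak")[2], 1)

  # dominance and monotonicity on random p vectors
  set.seed(3)
  for (i in 1:20) {
    p <- runif(sample(2:6, 1))
    a <- ldscope:::adjustStepDown(p, "sidak")
    expect_true(all(a >= p - 1e-15))
    expect_true(all(diff(a[order(p)]) > -1e-12))
    expect_true(all(a <= 1))
    # holm flag routes through the classical adjustment
    expect_equal(ldscope:::adjustStepDown(p, "holm"),
                 p.adjust(p, method = "holm"), tolerance = 1e-12)
  }
})

test_that("pairwise t statistics use the pooled residual mean square", {
  tab <- expand.grid(strain = c("A", "B", "C"),
                     experiment_id = paste0("E", 1:4),
                     stringsAsFactors = FALSE)
  set.seed(4)
  tab$value <- rnorm(12, rep(c(0, 1, 5), 4))
  an <- linkedAnova(tab)
  pw <- holmSidak(list(c("A", "B"), c("A", "C")), tab, an)
  means <- tapply(tab$value, tab$strain, mean)
  tExp <- (means["A"] - means["B"]) / sqrt(2 * an$msResidual / 4)
  expect_equal(pw$t[1], unname(tExp), tolerance = 1e-12)
  expect_equal(pw$df, c(6, 6))
  expect_equal(pw$p_raw, 2 * pt(-abs(pw$t), 6), tolerance = 1e-12)
  expect_error(holmSidak(list(c("A", "Z")), tab, an), "unknown strain")
})

test_that("reports carry the star convention and round-trip as CSV", {
  expect_identical(pStars(c(0.004, 0.2, 0.04, 0.0004)),
                   c("**", "NS", "*", "***"))
  tab <- expand.grid(strain = c("A", "B"), experiment_id = paste0("E", 1:3),
                     stringsAsFactors = FALSE)
  tab$value <- c(1, 5, 1.1, 5.2, 0.9, 5.1)
  an <- linkedAnova(tab)
  pw <- holmSidak(list(c("A", "B")), tab, an)
  d <- withr::local_tempdir()
  writeStatsReport(pw, d, an)
  back <- read.csv(file.path(d, "pairwise.csv"))
  expect_equal(back$p_adjusted, pw$p_adjusted, tolerance = 1e-12)
  expect_identical(back$stars, pw$stars)
  expect_true(file.exists(file.path(d, "anova.csv")))
  # empty results: header-only CSV
  writeStatsReport(pw[0, ], d)
  expect_equal(nrow(read.csv(file.path(d, "pairwise.csv"))), 0)
})

test_that("type-I error of the linked ANOVA is calibrated at the null", {
  # all strains from one distribution; 200 Monte-Carlo tables
  set.seed(11)
  n <- 200
  rej <- logical(n)
  for (i in 1:n) {
    tab <- expand.grid(strain = c("A", "B"),
                       experiment_id = paste0("E", 1:3),
                       stringsAsFactors = FALSE)
    blockEff <- rnorm(3, 0, 0.5)
    tab$value <- rnorm(6, 2, 0.3) + blockEff[as.integer(factor(tab$experiment_id))]
    rej[i] <- linkedAnova(tab)$pValue < 0.05
  }
  band <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(mean(rej) - 0.05), band + 1e-9)
})
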