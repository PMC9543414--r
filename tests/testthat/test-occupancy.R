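test_that("threshold rules convert fractions to occupancy, boundaries inclusive", {
  ov <- overlap_from_list(list(
    sp_a = c(rainforest = 0.90, savannah = 0.10),
    sp_b = c(steppe = 0.15, rainforest = 0.85),
    sp_c = c(taiga = 0.05, rainforest = 0.95)))
  occ <- apply_occupancy_rules(ov)
  expect_equal(unname(unclass(occ)["sp_a", ]),
               as.integer(biome_codes() == "rainforest"))
  expect_equal(unclass(occ)["sp_b", "steppe"], c(steppe = 1L),
               ignore_attr = TRUE)  # "15% or more" is inclusive
  expect_equal(unclass(occ)["sp_c", "taiga"], c(taiga = 0L),
               ignore_attr = TRUE)
})

test_that("patch rule adds occupancy at >= 50% coverage of an isolated patch", {
  frac <- data.frame(species = "sp_a", biome = "taiga",
                     range_fraction = 0.05)
  frac2 <- rbind(frac, data.frame(species = "sp_a", biome = "rainforest",
                                  range_fraction = 0.95))
  patches <- data.frame(species = "sp_a", biome = "taiga",
                        patch_id = "p1", patch_fraction = 0.60)
  occ <- apply_occupancy_rules(overlap_table(frac2, patches = patches))
  expect_equal(unclass(occ)["sp_a", "taiga"], c(taiga = 1L),
               ignore_attr = TRUE)
  # below the patch threshold the fraction rule alone decides
  patches$patch_fraction <- 0.49
  occ2 <- apply_occupancy_rules(overlap_table(frac2, patches = patches))
  expect_equal(unclass(occ2)["sp_a", "taiga"], c(taiga = 0L),
               ignore_attr = TRUE)
})

test_that("species failing both rules are reported, excluded, or rescued", {
  ov <- overlap_from_list(list(
    sp_a = c(rainforest = 0.14, savannah = 0.13, steppe = 0.13,
             taiga = 0.12, tundra = 0.12, savannah = 0.13),
    sp_b = c(rainforest = 1)))
  occ <- apply_occupancy_rules(ov)
  expect_equal(attr(occ, "unplaced"), "sp_a")
  expect_equal(nrow(occ), 1L)
  occ2 <- apply_occupancy_rules(ov, rescue_max_biome = TRUE)
  expect_equal(nrow(occ2), 2L)
  expect_equal(attr(occ2, "rescued"), "sp_a")
  expect_equal(unclass(occ2)["sp_a", "rainforest"], c(rainforest = 1L),
               ignore_attr = TRUE)  # largest fraction wins
})

test_that("invalid fractions and unknown biomes are rejected by name", {
  expect_error(overlap_table(data.frame(species = "x", biome = "rainforest",
                                        range_fraction = 1.2)),
               "outside \\[0,1\\].*x")
  expect_error(overlap_table(data.frame(species = "x", biome = "moon",
                                        range_fraction = 0.5)),
               "unknown biome")
  expect_error(overlap_table(data.frame(
    species = c("x", "x"), biome = c("rainforest", "steppe"),
    range_fraction = c(0.9, 0.9))), "sum to > 1")
})

test_that("BSI equals row sums and categories follow the fixed cut points", {
  block <- rbind(rep(1, 8),              # 8 biomes -> extreme generalist
                 c(1, 1, 1, rep(0, 5)),  # 3 biomes -> semi-generalist
                 c(1, rep(0, 7)))        # 1 biome  -> specialist
  occ <- occ_from_block(block)
  prof <- compute_bsi(occ)
  expect_equal(prof$bsi, c(8L, 3L, 1L))
  expect_equal(prof$category,
               c("extreme-generalist", "semi-generalist", "specialist"))
  s <- attr(prof, "summary")
  expect_equal(sum(s$class_counts), nrow(occ))
  expect_equal(s$mean_bsi, 4)
  # semi-generalist boundaries: 2 and 4 are semi, 5 is extreme
  expect_equal(bsi_category(c(1, 2, 4, 5)),
               c("specialist", "semi-generalist", "semi-generalist",
                 "extreme-generalist"))
})

test_that("all-zero occupancy rows are an error naming the species", {
  m <- matrix(0L, 2, 10, dimnames = list(c("ok", "empty"), biome_codes()))
  m["ok", 1] <- 1L
  occ <- occupancy_matrix(m, allow_zero_rows = TRUE)
  expect_error(compute_bsi(occ), "empty")
  expect_error(occupancy_matrix(m), "empty")
})

test_that("specialist table counts inhabitants and specialists per biome", {
  block <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 1))
  occ <- occ_from_block(block)
  prof <- compute_bsi(occ)
  tab <- specialist_table(occ, prof)
  expect_equal(tab$n_inhabitants[1:3], c(2L, 2L, 1L))
  expect_equal(tab$n_specialists[1:3], c(1L, 0L, 0L))
  expect_equal(tab$proportion_specialists[1], 0.5)
  expect_true(all(tab$proportion_specialists >= 0 &
                    tab$proportion_specialists <= 1))
  # empty biome columns: proportion 0 and flagged
  expect_true(all(tab$empty[4:10]))
  expect_equal(tab$proportion_specialists[4:10], rep(0, 7))
  # every specialist occupies exactly one biome, so per-biome specialist
  # counts sum to the total specialist count
  expect_equal(sum(tab$n_specialists), sum(prof$bsi == 1))
})

test_that("raising the range threshold never increases any BSI", {
  set.seed(42)
  for (rep in 1:20) {
    frac <- matrix(stats::rexp(10 * 10), 10, 10)
    frac <- frac / rowSums(frac)
    rownames(frac) <- sprintf("s%02d", 1:10)
    colnames(frac) <- biome_codes()
    ov <- overlap_table(data.frame(species = rownames(frac), frac,
                                   check.names = FALSE))
    lo <- apply_occupancy_rules(ov, range_threshold = 0.10,
                                rescue_max_biome = TRUE)
    hi <- apply_occupancy_rules(ov, range_threshold = 0.25,
                                rescue_max_biome = TRUE)
    bsi_lo <- rowSums(unclass(lo))
    bsi_hi <- rowSums(unclass(hi))
    # rescue keeps every species; higher threshold cannot add biomes
    expect_true(all(bsi_hi[names(bsi_lo)] <= bsi_lo))
  }
})

test_that("without patch records the rules reduce to fraction thresholding", {
  set.seed(7)
  frac <- matrix(stats::runif(50, 0, 0.4), 5, 10,
                 dimnames = list(sprintf("s%d", 1:5), biome_codes()))
  frac <- frac / pmax(rowSums(frac), 1)
  ov <- overlap_table(data.frame(species = rownames(frac), frac,
                                 check.names = FALSE))
  occ <- apply_occupancy_rules(ov, rescue_max_biome = TRUE)
  direct <- (frac >= 0.15) * 1L
  keep <- rowSums(direct) > 0
  expect_equal(unclass(occ)[keep, ], direct[keep, ], ignore_attr = TRUE)
})

test_that("occupancy CSV round trip preserves the matrix and thresholds", {
  block <- rbind(c(1, 0, 1), c(0, 1, 0))
  occ <- occ_from_block(block)
  attr(occ, "thresholds") <- c(range = 0.15, patch = 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_occupancy_csv(occ, f)
  expect_match(readLines(f, n = 1), "thresholds")
  back <- read_occupancy_csv(f)
  expect_equal(unclass(back), unclass(occ), ignore_attr = TRUE)
})

test_that("long and wide overlap CSV layouts load identically", {
  wide <- data.frame(species = c("a", "b"),
                     matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2),
                     check.names = FALSE)
  names(wide)[2:3] <- c("rainforest", "steppe")
  long <- data.frame(species = c("a", "a", "b", "b"),
                     biome = c("rainforest", "steppe", "rainforest",
                               "steppe"),
                     range_fraction = c(0.9, 0.1, 0.2, 0.8))
  names(wide)[2:3] <- c("rainforest", "steppe")
  fw <- withr::local_tempfile(fileext = ".csv")
  fl <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(wide, fw, row.names = FALSE)
  utils::write.csv(long, fl, row.names = FALSE)
  expect_equal(read_overlap_csv(fw)$fractions,
               read_overlap_csv(fl)$fractions)
})
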