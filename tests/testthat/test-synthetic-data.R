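test_that("configuration validation refuses out-of-range parameters", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(de_fraction = 1.5), "de_fraction")
  expect_error(sim_config(nb_dispersion = -1), ">= 0")
  expect_error(sim_config(n_genes = 50, de_fraction = 0.001), ">= 1")
  expect_error(sim_config(cohort_size = 5), ">= 10")
})

test_that("the same seed reproduces the genome byte for byte", {
  g1 <- simulate_genome(2, 3000, 8, seed = 7)
  g2 <- simulate_genome(2, 3000, 8, seed = 7)
  g3 <- simulate_genome(2, 3000, 8, seed = 8)
  expect_identical(g1, g2)
  expect_false(identical(g1$sequences, g3$sequences))
})

test_that("transcripts are in bounds, non-overlapping and named by gene", {
  g <- simulate_genome(2, 5000, 11, seed = 9)
  a <- g$annotation
  expect_equal(sort(a$name), sprintf("g%04d.t1", 1:11))
  expect_true(all(a$start >= 0))
  expect_true(all(a$end <= nchar(g$sequences)[a$chrom]))
  for (ch in unique(a$chrom)) {
    b <- a[a$chrom == ch, ]
    b <- b[order(b$start), ]
    if (nrow(b) > 1)
      expect_true(all(b$start[-1] >= b$end[-nrow(b)]))
  }
  expect_false(any(grepl("[^ACGT]", g$sequences)))
})

test_that("every simulated transcript carries a usable sense-strand site", {
  for (sd in 1:5) {
    g <- simulate_genome(1, 4000, 10, seed = sd)
    cat <- build_tag_catalog(g)
    expect_length(cat$no_canonical, 0)
    expect_equal(sum(cat$tags$is_canonical), 10)
  }
})

test_that("background sequence has the uniform-random CATG frequency", {
  # 2 transcripts on 10 kb leave the bulk of the sequence untouched;
  # expected site count is ~ L/256 with binomial spread
  n_sites <- 0; total <- 0
  for (sd in 1:5) {
    g <- simulate_genome(1, 10000, 2, seed = 100 + sd)
    n_sites <- n_sites +
      sum(gregexpr("CATG", g$sequences, fixed = TRUE)[[1]] > 0)
    total <- total + nchar(g$sequences)
  }
  expected <- total / 256
  sdev <- sqrt(expected)
  expect_gt(n_sites, expected - 4 * sdev)
  expect_lt(n_sites, expected + 4 * sdev + 10)   # + planted sites
})

test_that("count matrices have the declared shape and integer support", {
  cfg <- sim_config(seed = 3, n_genes = 100, n_patients = 6,
                    library_size = 2e4, de_fraction = 0.2)
  st <- simulate_paired_counts(cfg)
  expect_equal(dim(st$normal), c(100, 6))
  expect_equal(dimnames(st$tumor), list(st$genes, st$patients))
  expect_true(all(st$normal >= 0), all(st$normal == round(st$normal)))
  expect_identical(st$normal, simulate_paired_counts(cfg)$normal)
})

test_that("planted effects hit the declared genes, patients and folds", {
  cfg <- sim_config(seed = 3, n_genes = 100, n_patients = 6,
                    library_size = 2e4, de_fraction = 0.2,
                    planted_log2fc = 3, recurrence = 0.7)
  st <- simulate_paired_counts(cfg)
  expect_equal(sum(st$truth$is_de), 20)          # round(0.2 * 100)
  expect_equal(unique(st$truth$n_affected[st$truth$is_de]), 5)  # ceiling(4.2)
  expect_true(all(st$truth$n_affected[!st$truth$is_de] == 0))
  up <- st$truth$is_de & st$truth$sign == 1
  aff <- st$affected[up, , drop = FALSE]
  ratio <- sum(st$tumor[up, ][aff]) / sum(st$normal[up, ][aff])
  expect_equal(ratio, 8, tolerance = 0.15)       # 2^3 on affected cells
  null_cells <- !st$affected & matrix(TRUE, nrow(st$affected), ncol(st$affected))
  expect_equal(sum(st$tumor[null_cells]) / sum(st$normal[null_cells]), 1,
               tolerance = 0.05)
})

test_that("dispersion zero is Poisson-like, positive dispersion overdisperses", {
  base <- list(seed = 4, n_genes = 20, n_patients = 100,
               library_size = 1e4, de_fraction = 0.1)
  st_p <- simulate_paired_counts(do.call(sim_config, base))
  st_nb <- simulate_paired_counts(do.call(sim_config,
                                          c(base, nb_dispersion = 0.5)))
  vm <- function(st) {
    m <- rowMeans(st$normal); v <- apply(st$normal, 1, var)
    mean((v / m)[m > 50])
  }
  expect_lt(vm(st_p), 1.5)
  expect_gt(vm(st_nb), 5)                        # var = mu + 0.5 mu^2
})

test_that("a library smaller than the gene count warns", {
  expect_warning(
    simulate_paired_counts(sim_config(n_genes = 100, library_size = 50,
                                      de_fraction = 0.1)),
    "library_size")
})

test_that("error-free tag emission reproduces the counts exactly", {
  cfg <- sim_config(seed = 5, n_genes = 30, n_patients = 2,
                    library_size = 3000, de_fraction = 0.1,
                    tag_error_rate = 0)
  g <- simulate_genome(1, 30 * 450, 30, seed = cfg$seed)
  cat <- build_tag_catalog(g)
  st <- simulate_paired_counts(cfg)
  tags <- simulate_tags(st, cat, tag_error_rate = 0, seed = 6)
  expect_named(tags, c("P01_normal", "P01_tumor", "P02_normal", "P02_tumor"))
  canon <- cat$tags[cat$tags$is_canonical, ]
  lib <- tags$P01_normal
  expect_true(all(lib$tag %in% canon$sequence))
  expect_equal(sum(lib$count), sum(st$normal[, 1]))
  got <- setNames(lib$count, canon$gene_id[match(lib$tag, canon$sequence)])
  want <- st$normal[, 1][st$normal[, 1] > 0]
  # non-unique canonical 21-mers (if any) merge; compare the unique ones
  uni <- names(want)[names(want) %in% canon$gene_id[canon$is_unique]]
  expect_equal(got[uni], want[uni])
})

test_that("the per-read error fraction matches the binomial expectation", {
  cfg <- sim_config(seed = 5, n_genes = 50, n_patients = 2,
                    library_size = 5000, de_fraction = 0.1)
  g <- simulate_genome(1, 50 * 450, 50, seed = cfg$seed)
  cat <- build_tag_catalog(g)
  st <- simulate_paired_counts(cfg)
  tags <- simulate_tags(st, cat, tag_error_rate = 0.002, seed = 7)
  canon_seq <- cat$tags$sequence[cat$tags$is_canonical]
  err <- vapply(tags, function(l)
    sum(l$count[!l$tag %in% canon_seq]), numeric(1))
  tot <- vapply(tags, function(l) sum(l$count), numeric(1))
  p_exp <- 1 - (1 - 0.002)^21                    # = 0.04115
  expect_equal(sum(err) / sum(tot), p_exp, tolerance = 0.15)
  expect_identical(tags, simulate_tags(st, cat, 0.002, seed = 7))
})

test_that("tag emission refuses a catalog missing a gene's canonical tag", {
  cfg <- sim_config(seed = 5, n_genes = 3, n_patients = 1,
                    library_size = 100, de_fraction = 0.4)
  st <- simulate_paired_counts(cfg)
  small_cat <- catalog_from_tags(random_tags(2, seed = 8))
  expect_error(simulate_tags(st, small_cat, 0, seed = 1),
               "no canonical tag.*g0003")
})

test_that("the cohort carries consistent staining scores and groups", {
  cfg <- sim_config(seed = 2)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh), 103)
  expect_identical(coh, simulate_cohort(cfg))
  for (m in c("ALDH2", "CCNE1", "SMAD3")) {
    sc <- staining_index(coh[[paste0(m, "_pct")]],
                         coh[[paste0(m, "_intensity")]])
    expect_equal(coh[[paste0(m, "_index")]], sc$staining_index)
    expect_equal(coh[[paste0(m, "_group")]], sc$group)
  }
  expect_true(all(coh$time >= 1 & coh$time == round(coh$time)))
  expect_true(all(coh$event %in% 0:1))
  expect_true(all(levels(coh$t_stage) == c("T1", "T2", "T3")))
  n_risk <- attr(coh, "n_risk")
  expect_equal(n_risk,
               rowSums(cbind(coh$ALDH2_group == "low",
                             coh$CCNE1_group == "high",
                             coh$SMAD3_group == "high")))
})

test_that("high-risk marker states shorten observed survival", {
  coh <- simulate_cohort(sim_config(seed = 2))
  n_risk <- attr(coh, "n_risk")
  expect_gt(mean(coh$time[n_risk == 0]), mean(coh$time[n_risk >= 2]))
  cens <- 1 - mean(coh$event)
  expect_gt(cens, 0.1); expect_lt(cens, 0.55)
})
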