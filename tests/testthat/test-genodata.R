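test_that("PED/MAP reading codes minor-allele counts and missing genotypes", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines(c("1\trs1\t0\t100", "1\trs2\t0\t200"), map)
  writeLines(c("F1 A 0 0 0 -9 A A A G",
               "F2 B 0 0 0 -9 G G 0 0"), ped)
  ds <- read_ped_map(ped, map)
  expect_equal(ds$samples, c("A", "B"))
  # rs1: alleles A (2 copies in A) + G (2 in B): tie -> allele_b = "A" (lexicographic)
  expect_equal(ds$variants$allele_b[1], "A")
  expect_equal(unname(ds$genotypes[, 1]), c(2L, 0L))
  # rs2: only sample A genotyped, het; B missing
  expect_equal(unname(ds$genotypes[2, 2]), NA_integer_)
  expect_equal(unname(ds$genotypes[1, 2]), 1L)
})

test_that("ragged PED lines and three-allele sites are rejected by line/SNP", {
  ped <- tempfile(fileext = ".ped")
  map <- tempfile(fileext = ".map")
  writeLines("1\trs1\t0\t100", map)
  writeLines(c("F1 A 0 0 0 -9 A A", "F2 B 0 0 0 -9 A"), ped)
  expect_error(read_ped_map(ped, map), "line 2")
  writeLines(c("F1 A 0 0 0 -9 A C", "F2 B 0 0 0 -9 G G"), ped)
  expect_error(read_ped_map(ped, map), "more than two alleles")
})

test_that("write/read round-trip preserves codes, IDs and variant order", {
  for (seed in 1:3) {
    ds <- random_ds(10, 50, seed = seed, miss = 0.1)
    ped <- tempfile(fileext = ".ped")
    map <- tempfile(fileext = ".map")
    write_ped_map(ds, ped, map)
    back <- read_ped_map(ped, map)
    expect_equal(back$samples, ds$samples)
    expect_equal(back$variants$snp_id, ds$variants$snp_id)
    # codes agree up to the minor-allele orientation chosen on re-read
    # (at an exact 50/50 tie the lexicographically smaller written allele
    # "A" becomes allele_b, flipping codes)
    p <- allele_freqs(ds)
    flip <- !is.na(p) & p >= 0.5
    expected <- ds$genotypes
    expected[, flip] <- 2L - expected[, flip]
    mono <- apply(ds$genotypes, 2, function(col) {
      col <- col[!is.na(col)]
      length(col) == 0 || all(col == col[1])
    })
    expect_equal(unname(back$genotypes[, !mono]), unname(expected[, !mono]))
  }
  # empty dataset round-trips
  empty <- subset_dataset(random_ds(3, 4, seed = 1), samples = integer(0))
  ped <- tempfile(); map <- tempfile()
  write_ped_map(empty, ped, map)
  back <- read_ped_map(ped, map)
  expect_equal(n_samples(back), 0L)
  expect_equal(n_variants(back), 4L)
})

test_that("single het sample writes two different allele characters", {
  ds <- make_ds(matrix(1L, 1, 1))
  ped <- tempfile(); map <- tempfile()
  write_ped_map(ds, ped, map)
  alleles <- strsplit(readLines(ped), " ")[[1]][7:8]
  expect_length(unique(alleles), 2)
})

test_that("metadata reading validates regions and latitudes", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample_id,state,region,latitude",
               "S1,Kelantan (Jeli),North,5.497056",
               "S2,Singapore (Malay),South,1.287043"), path)
  md <- read_metadata(path)
  expect_equal(md$latitude, c(5.497056, 1.287043))
  writeLines(c("sample_id,state,region,latitude",
               "S1,Kelantan (Jeli),Norther,5.497056"), path)
  expect_error(read_metadata(path), "region")
  writeLines(c("sample_id,state,region,latitude",
               "S1,Kelantan (Jeli),North,91.0"), path)
  expect_error(read_metadata(path), "latitude")
})

test_that("packaged state lookup reproduces the regional sample totals", {
  tab <- state_region_table()
  expect_setequal(unique(tab$region), REGIONS)
  totals <- tapply(tab$n_subjects, tab$region, sum, na.rm = TRUE)
  expect_equal(as.numeric(totals[c("North", "Centre", "South")]),
               c(146, 149, 107))
  expect_equal(region_of_state(c("Johor", "Perlis", "Selangor")),
               c("South", "North", "Centre"))
})

test_that("merge intersects SNPs, harmonizes swapped alleles, pools frequencies", {
  v1 <- data.frame(snp_id = paste0("s", 1:5), chrom = "1", pos = 1:5 * 100,
                   allele_a = "A", allele_b = "G")
  v2 <- data.frame(snp_id = paste0("s", 3:7), chrom = "1", pos = 3:7 * 100,
                   allele_a = "A", allele_b = "G")
  ds1 <- genotype_dataset(matrix(0:1, 2, 5), c("x1", "x2"), v1)
  ds2 <- genotype_dataset(matrix(1:2, 2, 5), c("y1", "y2"), v2)
  merged <- merge_datasets(list(ds1, ds2))
  expect_equal(n_variants(merged), 3)
  expect_equal(merged$samples, c("x1", "x2", "y1", "y2"))

  # swapped allele labels flip codes g -> 2 - g
  v2s <- v2
  v2s$allele_a[1] <- "G"; v2s$allele_b[1] <- "A"  # s3 swapped
  ds2s <- genotype_dataset(matrix(1:2, 2, 5), c("y1", "y2"), v2s)
  merged_s <- merge_datasets(list(ds1, ds2s))
  expect_equal(unname(merged_s$genotypes[3:4, "s3"]),
               2L - unname(merged$genotypes[3:4, "s3"]))

  # incompatible pair beyond a swap
  v2b <- v2
  v2b$allele_b[2] <- "C"  # s4: A/C vs A/G
  ds2b <- genotype_dataset(matrix(1:2, 2, 5), c("y1", "y2"), v2b)
  expect_error(merge_datasets(list(ds1, ds2b)), "s4")

  # pooled frequencies equal brute-force pooled counts across three datasets
  mk <- function(seed, ids) {
    set.seed(seed)
    g <- matrix(rbinom(4 * 6, 2, 0.4), 4, 6)
    genotype_dataset(g, ids, data.frame(snp_id = paste0("s", 1:6), chrom = "1",
                                        pos = 1:6, allele_a = "A",
                                        allele_b = "G"))
  }
  parts <- list(mk(1, paste0("a", 1:4)), mk(2, paste0("b", 1:4)),
                mk(3, paste0("c", 1:4)))
  pooled <- merge_datasets(parts)
  brute <- colSums(do.call(rbind, lapply(parts, function(d) d$genotypes))) / (2 * 12)
  expect_equal(unname(allele_freqs(pooled)), unname(brute))

  # symmetric in variant content: order permutes samples only
  rev_merge <- merge_datasets(list(ds2, ds1))
  expect_setequal(rev_merge$variants$snp_id, merged$variants$snp_id)
  expect_setequal(rev_merge$samples, merged$samples)
})

test_that("allele counts tally non-missing genotypes and bound invariants hold", {
  ds <- make_ds(matrix(c(0L, 1L, 2L), 3, 1))
  ac <- allele_counts(ds, "s001")
  expect_equal(ac$n_genotyped, 3)
  expect_equal(ac$count_b, 3)
  expect_equal(ac$count_het, 1)

  ds_na <- make_ds(matrix(NA_integer_, 3, 1))
  ac_na <- allele_counts(ds_na, "s001")
  expect_equal(ac_na$n_genotyped, 0)

  expect_error(allele_counts(ds, "nope"), "unknown snp_id")
  expect_error(allele_counts_raw(2, 5, 0), "count_b")
  expect_error(allele_counts_raw(3, 2, 3), "count_het")

  for (seed in 1:5) {
    set.seed(seed)
    col <- sample(c(0L, 1L, 2L, NA), 30, replace = TRUE)
    ds_r <- make_ds(matrix(col, ncol = 1))
    ac_r <- allele_counts(ds_r, "s001")
    expect_equal(ac_r$n_genotyped, sum(!is.na(col)))
    expect_equal(ac_r$count_b, sum(col, na.rm = TRUE))
    expect_equal(ac_r$count_het, sum(col == 1, na.rm = TRUE))
    p <- ac_r$count_b / (2 * ac_r$n_genotyped)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})
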