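make_map3 <- function() {
  new_map <- digest_genome(c(chrA = "CCGAATTCAAGAATTCGG"),
                           enzyme_registry("EcoRI"))
  new_map
}

test_that("reads increment the fragment containing their 5' position", {
  m <- make_map3()
  reads <- data.frame(chrom = "chrA", pos = c(1, 4, 4))
  cts <- count_reads(reads, m)
  expect_equal(cts$raw, c(1L, 2L, 0L))
  expect_equal(attr(cts, "total_mapped_reads"), 3L)

  # off-map chromosome is tallied, not fatal
  reads2 <- data.frame(chrom = c("chrA", "chrZ"), pos = c(1, 5))
  cts2 <- count_reads(reads2, m)
  expect_equal(attr(cts2, "off_map_reads"), 1L)
  expect_equal(sum(cts2$raw) + attr(cts2, "off_map_reads"),
               attr(cts2, "total_mapped_reads"))  # count conservation
})

test_that("random read assignment equals an interval-membership brute force", {
  set.seed(5)
  m <- make_map3()
  pos <- sample(0:17, 1000, replace = TRUE)
  cts <- count_reads(data.frame(chrom = "chrA", pos = pos), m)
  brute <- vapply(seq_len(nrow(m)), function(i)
    sum(pos >= m$start[i] & pos < m$end[i]), integer(1))
  expect_equal(cts$raw, brute)
})

test_that("RPKM follows its definition and guards a zero total", {
  m <- make_map3()
  cts <- count_reads(data.frame(chrom = character(0), pos = numeric(0)), m)
  expect_error(normalize_rpkm(cts), "> 0")

  # raw 10, length 500 bp, total 2e6 -> 10 / (0.5 * 2) = 10
  df <- data.frame(fragment_id = 1L, chrom = "c", start = 0, end = 500,
                   raw = 10L, rpkm = NA_real_, excluded = FALSE)
  sc <- loop4c:::new_sample_counts(df, sample_id = "s",
                                   total_mapped_reads = 2e6)
  expect_equal(normalize_rpkm(sc)$rpkm, 10)
  df2 <- transform(df, end = 1000, raw = 50L)
  sc2 <- loop4c:::new_sample_counts(df2, sample_id = "s",
                                    total_mapped_reads = 1e6)
  expect_equal(normalize_rpkm(sc2)$rpkm, 50)
  df3 <- transform(df, raw = 0L)
  sc3 <- loop4c:::new_sample_counts(df3, sample_id = "s",
                                    total_mapped_reads = 123456)
  expect_equal(normalize_rpkm(sc3)$rpkm, 0)
})

test_that("RPKM is invariant to doubling counts and total together", {
  set.seed(8)
  m <- make_map3()
  cts <- count_reads(data.frame(chrom = "chrA",
                                pos = sample(0:17, 200, replace = TRUE)), m)
  a <- normalize_rpkm(cts)
  b <- cts; b$raw <- b$raw * 2L
  attr(b, "total_mapped_reads") <- attr(cts, "total_mapped_reads") * 2L
  expect_equal(normalize_rpkm(b)$rpkm, a$rpkm)
})

test_that("bait-proximal exclusion takes the bait and n fragments per side", {
  map <- simulate_fragment_map("chrA", 100000, 30, seed = 1)
  map <- locate_bait(map, bait_config("b", "chrA", map$start[11]))
  cts <- count_reads(data.frame(chrom = character(0), pos = numeric(0)), map)
  attr(cts, "total_mapped_reads") <- 1L

  ex <- attr(exclude_bait_proximal(cts, 2), "excluded_fragment_ids")
  expect_equal(ex, 9:13)
  expect_equal(attr(exclude_bait_proximal(cts, 0),
                    "excluded_fragment_ids"), 11L)

  # truncation at the chromosome start
  map0 <- locate_bait(map, bait_config("b", "chrA", 0))
  cts0 <- count_reads(data.frame(chrom = character(0), pos = numeric(0)), map0)
  expect_equal(attr(exclude_bait_proximal(cts0, 2),
                    "excluded_fragment_ids"), 1:3)

  # monotone in n_exclude
  sets <- lapply(0:5, function(n)
    attr(exclude_bait_proximal(cts, n), "excluded_fragment_ids"))
  for (i in 2:length(sets))
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
})

test_that("cis fraction is reads-on-bait-chromosome over mapped reads", {
  df <- data.frame(fragment_id = 1:2, chrom = c("chrA", "chrB"),
                   start = c(0, 0), end = c(1000, 1000),
                   raw = c(45L, 55L), rpkm = NA_real_, excluded = FALSE)
  sc <- loop4c:::new_sample_counts(df, sample_id = "s",
                                   total_mapped_reads = 100L)
  f <- cis_fraction(sc, "chrA")
  expect_equal(as.numeric(f), 0.45)
  expect_true(attr(f, "pass"))
  df$raw <- c(39L, 61L)
  sc2 <- loop4c:::new_sample_counts(df, sample_id = "s",
                                    total_mapped_reads = 100L)
  expect_false(attr(cis_fraction(sc2, "chrA"), "pass"))
  df$raw <- c(100L, 0L)
  sc3 <- loop4c:::new_sample_counts(df, sample_id = "s",
                                    total_mapped_reads = 100L)
  expect_equal(as.numeric(cis_fraction(sc3, "chrA")), 1.0)
  df$raw <- c(0L, 0L)
  sc4 <- loop4c:::new_sample_counts(df, sample_id = "s",
                                    total_mapped_reads = 0L)
  expect_error(cis_fraction(sc4, "chrA"), "no mapped reads")
})

test_that("count tables round-trip with metadata", {
  cfg <- sim_config(n_cis_fragments = 60, cis_length = 3e5,
                    n_trans_fragments = 30, trans_length = 1e5,
                    planted_cis = NULL, planted_trans = NULL,
                    diets = "CD", timepoints = "ZT6")
  map <- simulate_map(cfg, seed = 2)
  sim <- simulate_counts(map, cfg, seed = 2)
  sc <- sim$samples[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(sc, path)
  back <- read_count_table(path)
  expect_equal(back$raw, sc$raw)
  expect_equal(back$rpkm, sc$rpkm, tolerance = 1e-8)
  expect_equal(attr(back, "diet"), "CD")
  expect_equal(attr(back, "total_mapped_reads"),
               attr(sc, "total_mapped_reads"))
  expect_equal(attr(back, "bait_fragment_id"), attr(sc, "bait_fragment_id"))
})

test_that("BAM reading agrees with the data-frame path", {
  m <- simulate_fragment_map("chrA", 10000, 5, seed = 9)
  pos <- c(10L, 2500L, 2500L, 9000L)
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chrA\tLN:10000",
           sprintf("r%d\t0\tchrA\t%d\t60\t30M\t*\t0\t0\t%s\t*",
                   seq_along(pos), pos + 1L,
                   strrep("A", 30)))
  sam_path <- withr::local_tempfile(fileext = ".sam")
  writeLines(sam, sam_path)
  bam_path <- Rsamtools::asBam(sam_path,
                               destination = sub("\\.sam$", "", sam_path),
                               overwrite = TRUE)
  via_bam <- count_reads(bam_path, m)
  via_df <- count_reads(data.frame(chrom = "chrA", pos = pos), m)
  expect_equal(via_bam$raw, via_df$raw)
})
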