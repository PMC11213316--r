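test_that("probe annotation loads, sorts per chromosome and validates columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,chrom,pos", "cg1,chr1,100", "cg2,chr1,50", "cg3,chr2,10"), f)
  lay <- load_probe_annotation(f, "manifest_csv")
  expect_s3_class(lay, "array_layout")
  expect_equal(lay$pos[lay$chrom == "chr1"], c(50, 100))
  expect_equal(lay$pos[lay$chrom == "chr2"], 10)
  # sorting is idempotent: rebuilding from the loaded table changes nothing
  expect_equal(as.data.frame(array_layout(lay$probe_id, lay$chrom, lay$pos)),
               as.data.frame(lay))

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("probe_id,chrom", "cg1,chr1"), f2)
  expect_error(load_probe_annotation(f2, "manifest_csv"), "pos")

  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t100\tcg1", "chr1\t49\t50\tcg2"), f3)
  bed <- load_probe_annotation(f3, "bed3plus")
  expect_equal(sort(bed$pos), c(50, 100))  # 0-based starts converted to 1-based
})

test_that("layout construction rejects duplicates and drops missing coordinates", {
  expect_error(array_layout(c("a", "a"), c("chr1", "chr1"), c(1, 2)), "duplicated")
  expect_message(lay <- array_layout(c("a", "b"), c("chr1", NA), c(1, 2)), "dropped")
  expect_equal(nrow(lay), 1L)
  expect_error(array_layout(character(0), character(0), numeric(0)), "empty")
  expect_error(array_layout("a", "chr1", 0), ">= 1")
})

test_that("chromosome gaps follow adjacent-position differences", {
  lay <- tiny_layout(list(chr1 = c(100, 300, 350, 900), chr2 = c(10, 10), chr3 = 5))
  expect_equal(chromosome_gaps(lay, "chr1"), c(200, 50, 550))
  expect_equal(chromosome_gaps(lay, "chr2"), 0)      # duplicate coordinate
  expect_equal(chromosome_gaps(lay, "chr3"), numeric(0))
})

test_that("median gap uses the even-count mean convention and shifts cancel", {
  lay <- tiny_layout(list(chr1 = c(100, 300, 350, 900)))
  expect_equal(median_gap(lay, "chr1"), 200)
  lay2 <- tiny_layout(list(chr1 = c(0, 100, 400) + 1))   # gaps 100, 300
  expect_equal(median_gap(lay2, "chr1"), 200)
  lay3 <- tiny_layout(list(chr1 = cumsum(rep(42, 6))))
  expect_equal(median_gap(lay3, "chr1"), 42)
  # invariance under translating all positions
  shifted <- tiny_layout(list(chr1 = c(100, 300, 350, 900) + 12345))
  expect_equal(median_gap(shifted, "chr1"), median_gap(lay, "chr1"))
})

test_that("bandwidth policies map chromosomes to fixed or median-gap bandwidths", {
  lay <- tiny_layout(list(chr1 = c(100, 300, 350, 900), chr2 = c(10, 510)))
  pf <- make_bandwidth_policy(lay, "fixed", fixed_h = 500)
  expect_equal(unname(pf$h), c(500, 500))
  pa <- make_bandwidth_policy(lay, "adaptive")
  expect_equal(pa$h[["chr1"]], 200)
  expect_equal(pa$h[["chr2"]], 500)
  # single-probe chromosome falls back to fixed_h with a warning
  lay1 <- tiny_layout(list(chr1 = c(100, 200, 300), chrY = 77))
  expect_warning(p1 <- make_bandwidth_policy(lay1, "adaptive"), "falling back")
  expect_equal(p1$h[["chrY"]], 500)
  # perfectly uniform layout: adaptive bandwidth equals the constant gap
  layu <- tiny_layout(list(chr1 = seq(1, by = 250, length.out = 40)))
  expect_equal(make_bandwidth_policy(layu, "adaptive")$h[["chr1"]], 250)
  expect_error(make_bandwidth_policy(lay, "fixed", fixed_h = -1), "> 0")
})

test_that("layout emulator is reproducible and conserves probe counts", {
  cfg <- layout_config(probes_per_chrom = c(chr1 = 600, chr2 = 400))
  a <- emulate_layout(cfg, seed = 99)
  b <- emulate_layout(cfg, seed = 99)
  expect_identical(a, b)
  expect_equal(nrow(a), 1000L)
  expect_equal(sum(a$chrom == "chr1"), 600L)
  reg <- candidate_regions(a)
  expect_true(all(reg$n_probes >= 4))
  # member probes lie within their region bounds
  memb <- a[!is.na(a$region_id), ]
  expect_true(all(memb$pos >= reg$start[match(memb$region_id, reg$region_id)]))
  expect_true(all(memb$pos <= reg$end[match(memb$region_id, reg$region_id)]))
  # regions are non-overlapping within a chromosome
  for (ch in unique(reg$chrom)) {
    r <- reg[reg$chrom == ch, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
  }
})

test_that("emulated gap distribution is island-dominated with a heavy right tail", {
  cfg <- layout_config(probes_per_chrom = c(chr1 = 4000),
                       island_weight = 0.7,
                       island_meanlog = log(50), opensea_meanlog = log(5000))
  lay <- emulate_layout(cfg, seed = 3)
  gaps <- chromosome_gaps(lay, "chr1")
  expect_lt(median(gaps), 1000)          # island component dominates the median
  expect_gt(mean(gaps), median(gaps))    # right-skewed
  expect_gt(max(gaps), 5000)             # heavy open-sea tail
  # mode of the distribution sits below 200 bp
  h <- hist(gaps[gaps <= 1000], breaks = seq(0, 1000, by = 100), plot = FALSE)
  expect_lt(h$mids[which.max(h$counts)], 200)
  expect_error(layout_config(probes_per_chrom = c(chr1 = -5)), "positive")
})

test_that("gap histogram export covers all gaps", {
  lay <- small_emulated_layout(n_chrom = 1, probes = 500L)
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- write_gap_histogram(lay, f)
  expect_equal(sum(out$count), 499L)
  expect_true(file.exists(f))
})
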