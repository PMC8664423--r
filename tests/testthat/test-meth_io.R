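test_that("bedGraph rows map to site counts and preserve order", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t101\t80.0\t8\t2",
               "chr1\t200\t201\t0.0\t0\t5",
               "chr2\t50\t51\t100.0\t3\t0"), path)
  tb <- read_site_counts(path)
  expect_equal(nrow(tb), 3L)
  expect_equal(tb$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(tb$pos, c(100L, 200L, 50L))
  expect_equal(tb$n_meth, c(8L, 0L, 3L))
  expect_equal(tb$n_total, c(10L, 5L, 3L))
})

test_that("malformed bedGraph rows raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t100\t101\t80.0\t8\t2", "chr1\t200\t201\t50.0"), path)
  expect_error(read_site_counts(path), "line 2")
  writeLines("chr1\t100\t101\t80.0\tx\t2", path)
  expect_error(read_site_counts(path), "line 1")
})

test_that("count tables round-trip through write and read exactly", {
  set.seed(42)
  tb <- data.frame(chrom = rep(c("chr1", "chr2"), each = 25),
                   pos = c(sort(sample.int(1e5, 25)),
                           sort(sample.int(1e5, 25))))
  tb$n_total <- rpois(50, 10) + 1L
  tb$n_meth <- rbinom(50, tb$n_total, 0.8)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_site_counts(tb, path)
  back <- read_site_counts(path)
  expect_equal(back$chrom, tb$chrom)
  expect_equal(back$pos, tb$pos)
  expect_equal(back$n_meth, tb$n_meth)
  expect_equal(back$n_total, tb$n_total)
})

test_that("build_matrix takes the union of sites with missing cells", {
  t1 <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                   n_meth = c(1L, 2L, 3L), n_total = c(4L, 5L, 6L))
  t2 <- data.frame(chrom = "chr1", pos = c(100L, 300L),
                   n_meth = c(0L, 6L), n_total = c(2L, 6L))
  m <- build_matrix(list(a = t1, b = t2))
  expect_equal(n_sites(m), 3L)
  expect_equal(sum(is.na(m$meth)), 1L)
  expect_true(is.na(m$total[m$pos == 200L, "b"]))
  # single sample: identity
  m1 <- build_matrix(list(a = t1))
  expect_equal(as.vector(m1$meth), t1$n_meth)
  # degenerate and invalid inputs
  expect_error(build_matrix(list()), "no sample tables")
  t_dup <- rbind(t1, t1[1, ])
  expect_error(build_matrix(list(a = t_dup)), "duplicate")
})

test_that("variant masking removes exactly the intersecting sites", {
  m <- mk_matrix("chr1", c(100L, 150L, 200L),
                 matrix(1L, 3, 2), matrix(2L, 3, 2))
  v <- data.frame(chrom = "chr1", start = 150L, end = 151L)
  expect_equal(mask_variant_sites(m, v)$pos, c(100L, 200L))
  expect_equal(mask_variant_sites(m, v[0, ])$pos, m$pos)
  v_all <- data.frame(chrom = "chr1", start = 0L, end = 300L)
  expect_equal(n_sites(mask_variant_sites(m, v_all)), 0L)
})

test_that("masking agrees with a brute-force per-site scan", {
  set.seed(7)
  n <- 200
  chr <- sample(c("chr1", "chr2"), n, TRUE)
  pos <- sample.int(5000, n)
  keys <- unique(data.frame(chrom = chr, pos = pos))
  m <- mk_matrix(keys$chrom, keys$pos,
                 matrix(1L, nrow(keys), 2), matrix(3L, nrow(keys), 2))
  v <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                  start = sample.int(5000, 20))
  v$end <- v$start + sample.int(100, 20)
  kept <- mask_variant_sites(m, v)
  inside <- vapply(seq_len(n_sites(m)), function(i)
    any(v$chrom == m$chrom[i] & m$pos[i] >= v$start & m$pos[i] < v$end),
    logical(1))
  expect_equal(kept$pos, m$pos[!inside])
  expect_equal(kept$chrom, m$chrom[!inside])
})

test_that("site filters implement the coverage and contig rules", {
  # 16 samples: 5-20x in 12 of them, 3x in 4 -> retained
  tot <- matrix(c(rep(10L, 12), rep(3L, 4)), 1, 16)
  met <- matrix(0L, 1, 16)
  m <- mk_matrix("chr1", 500L, met, tot)
  lens <- c(chr1 = 50000)
  expect_equal(n_sites(filter_sites(m, chrom_lengths = lens)), 1L)
  # a zero-coverage (missing) cell in one sample drops the site
  tot2 <- tot; tot2[1, 16] <- NA_integer_; met2 <- met; met2[1, 16] <- NA_integer_
  m2 <- mk_matrix("chr1", 500L, met2, tot2)
  expect_equal(n_sites(filter_sites(m2, chrom_lengths = lens)), 0L)
  # short contig drops the site regardless of coverage
  m3 <- mk_matrix("chr9", 500L, matrix(5L, 1, 16), matrix(10L, 1, 16))
  expect_equal(n_sites(filter_sites(m3, chrom_lengths = c(chr9 = 9000))), 0L)
  # coverage window is only satisfied by 11 of 16 -> dropped
  tot4 <- matrix(c(rep(10L, 11), rep(30L, 5)), 1, 16)
  m4 <- mk_matrix("chr1", 500L, matrix(0L, 1, 16), tot4)
  expect_equal(n_sites(filter_sites(m4, chrom_lengths = lens)), 0L)
  expect_error(filter_sites(m, min_frac_samples = 0),
               "min_frac_samples")
})

test_that("filter_sites is idempotent", {
  set.seed(11)
  n <- 300
  tot <- matrix(rpois(n * 8, 8), n, 8)
  met <- matrix(rbinom(n * 8, as.vector(tot), 0.7), n, 8)
  m <- mk_matrix(rep("chr1", n), sort(sample.int(1e5, n)), met, tot)
  lens <- c(chr1 = 1e5)
  f1 <- filter_sites(m, chrom_lengths = lens)
  f2 <- filter_sites(f1, chrom_lengths = lens)
  expect_equal(f1$pos, f2$pos)
  expect_equal(f1$meth, f2$meth)
})

test_that("region BED output is sorted and tab-separated", {
  path <- withr::local_tempfile(fileext = ".bed")
  regions <- data.frame(chrom = c("chr2", "chr1"),
                        start = c(500L, 100L), end = c(700L, 251L),
                        name = c("b", "DMR1"))
  write_regions_bed(regions, path)
  lines <- readLines(path)
  expect_match(lines[1], "^chr1\t100\t251\tDMR1\t")
  expect_equal(length(lines), 2L)
  write_regions_bed(regions[0, ], path)
  expect_equal(length(readLines(path)), 0L)
})
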