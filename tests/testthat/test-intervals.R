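toy_genome <- c(chrA = 1000, chrB = 800)

test_that("interval sets validate and merge correctly", {
  expect_error(interval_set("chrA", 10, 10, seqlengths = toy_genome), "invalid")
  expect_error(interval_set("chrA", 10, 2000, seqlengths = toy_genome),
               "beyond chromosome")
  expect_error(interval_set("chrZ", 1, 5, seqlengths = toy_genome), "absent")
  m <- merge_intervals(interval_set(c("chrA", "chrA"), c(0, 5), c(10, 20),
                                    seqlengths = toy_genome))
  expect_equal(m$intervals[, c("start", "end")],
               data.frame(start = 0, end = 20))
  # adjacent merge by default, preserved bases
  adj <- interval_set(c("chrA", "chrA"), c(0, 10), c(10, 20),
                      seqlengths = toy_genome)
  expect_equal(nrow(merge_intervals(adj)$intervals), 1L)
  expect_equal(nrow(merge_intervals(adj, adjacent = FALSE)$intervals), 2L)
  expect_equal(covered_bases(adj), 20)
  # disjoint input is untouched
  dis <- interval_set(c("chrA", "chrA"), c(0, 50), c(10, 60),
                      seqlengths = toy_genome)
  expect_equal(merge_intervals(dis)$intervals$start, c(0, 50))
})

test_that("intersection and coverage match hand computations", {
  a <- interval_set("chrA", 0, 100, seqlengths = toy_genome)
  b <- interval_set("chrA", 50, 150, seqlengths = toy_genome)
  expect_equal(intersect_intervals(a, b)$intervals$start, 50)
  expect_equal(intersect_intervals(a, b)$intervals$end, 100)
  expect_equal(coverage_fraction(a, b)$per_interval$fraction, 0.5)
  expect_equal(coverage_fraction(a, a)$per_interval$fraction, 1.0)
  disjoint <- interval_set("chrB", 0, 50, seqlengths = toy_genome)
  expect_equal(coverage_fraction(a, disjoint)$per_interval$fraction, 0)
  expect_equal(jaccard_index(a, b), 1 / 3)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, disjoint), 0)
  expect_warning(jaccard_index(interval_set(character(), numeric(), numeric(),
                                            seqlengths = toy_genome),
                               interval_set(character(), numeric(), numeric(),
                                            seqlengths = toy_genome)),
                 "empty union")
})

test_that("interval operations agree with the per-base bit-vector oracle", {
  set.seed(23)
  for (i in 1:40) {
    g <- c(c1 = sample(500:2000, 1), c2 = sample(500:2000, 1))
    a <- random_interval_set(sample(3:25, 1), g)
    b <- random_interval_set(sample(3:25, 1), g)
    expect_equal(covered_bases(a), oracle_covered(a))
    expect_equal(jaccard_index(a, b), oracle_jaccard(a, b))
    expect_equal(sum(with(intersect_intervals(a, b)$intervals, end - start)),
                 oracle_intersect_bases(a, b))
    expect_equal(coverage_fraction(a, b)$per_interval$fraction,
                 oracle_coverage_fraction(a, b))
    expect_equal(site_overlap_fraction(merge_intervals(a), b),
                 oracle_site_overlap(merge_intervals(a), b))
  }
})

test_that("projection test matches the closed-form binomial tail", {
  g <- c(chrA = 1000)
  ref <- interval_set("chrA", 0, 500, seqlengths = g)   # coverage 0.5
  q <- interval_set("chrA", seq(0, 450, by = 50), seq(20, 470, by = 50),
                    seqlengths = g)                     # 10 midpoints inside
  pt <- projection_test(q, ref)
  expect_equal(pt$k, 10L)
  expect_equal(pt$coverage, 0.5)
  expect_equal(pt$p_value, 2 * 0.5^10)
  # k/n == c exactly: central case, p >= 0.5
  ref2 <- interval_set("chrA", 0, 500, seqlengths = g)
  q2 <- interval_set("chrA", c(100, 700), c(120, 720), seqlengths = g)
  expect_gte(projection_test(q2, ref2)$p_value, 0.5)
  # reference covering the whole genome: k = n, p = 1
  all_ref <- interval_set("chrA", 0, 1000, seqlengths = g)
  expect_equal(projection_test(q, all_ref)$p_value, 1)
})

test_that("relative distances and area correlation behave at the extremes", {
  g <- c(chrA = 1000)
  ref <- interval_set("chrA", c(0, 100, 200, 300), c(2, 102, 202, 302),
                      seqlengths = g)
  # coinciding query: all relative distances 0, area correlation 1
  dc <- distance_correlation(ref, ref, n_perm = 19, seed = 1)
  expect_equal(dc$relative_ecdf_area_correlation, 1)
  # hand case: midpoint at 25 with flanks at 0 and 100 -> 0.25
  ref2 <- interval_set("chrA", c(0, 100), c(1, 101), seqlengths = g)
  q <- interval_set("chrA", 25, 26, seqlengths = g)
  d <- apmsflow:::rel_abs_distances(q, ref2)
  expect_equal(d$relative, 0.25)
  expect_equal(d$absolute, 25)
  # chromosomes with < 2 reference midpoints are skipped with a notice
  g2 <- c(chrA = 1000, chrB = 1000)
  ref3 <- interval_set(c("chrA", "chrA", "chrB"), c(0, 100, 5), c(1, 101, 6),
                       seqlengths = g2)
  q3 <- interval_set(c("chrA", "chrB"), c(25, 50), c(26, 51), seqlengths = g2)
  d3 <- apmsflow:::rel_abs_distances(q3, ref3)
  expect_equal(d3$skipped, "chrB")
  expect_length(d3$relative, 1L)
})

test_that("relocation nulls preserve interval counts and lengths per chromosome", {
  set.seed(3)
  x <- random_interval_set(40, toy_genome)
  y <- apmsflow:::with_seed(5, apmsflow:::relocate_intervals(x))
  for (chr in names(toy_genome)) {
    xi <- x$intervals[x$intervals$chrom == chr, ]
    yi <- y$intervals[y$intervals$chrom == chr, ]
    expect_equal(nrow(xi), nrow(yi))
    expect_equal(sort(xi$end - xi$start), sort(yi$end - yi$start))
    expect_true(all(yi$start >= 0 & yi$end <= toy_genome[chr]))
  }
})

test_that("planted correlation is detected; jaccard/identical/disjoint cases", {
  iv <- sim_intervals(simulation_spec(seed = 19, n_intervals = 250L))
  dc <- distance_correlation(iv$query, iv$reference, n_perm = 99, seed = 3)
  expect_gt(dc$relative_ecdf_area_correlation, 0.3)
  expect_lt(projection_test(iv$query, iv$reference)$p_value, 0.01)
  jt <- jaccard_test(iv$query, iv$reference, n_perm = 49, seed = 3)
  expect_equal(jt$p_value, 1 / 50)
  # identical sets after merge -> jaccard 1 (planted fraction 1, no jitter)
  iv2 <- sim_intervals(simulation_spec(seed = 19, n_intervals = 40L,
                                       planted_fraction = 1, jitter_sd = 0))
  expect_equal(jaccard_index(merge_intervals(iv2$query),
                             merge_intervals(iv2$reference)), 1)
})

test_that("partition annotation distributes site bases and sums to 100", {
  g <- c(chrA = 100)
  part <- interval_set(c("chrA", "chrA"), c(0, 50), c(50, 100),
                       label = c("A", "B"), seqlengths = g)
  sites <- interval_set("chrA", 40, 60, seqlengths = g)
  pc <- annotate_partition(sites, part)
  expect_equal(pc[["A"]], 50)
  expect_equal(pc[["B"]], 50)
  inA <- interval_set("chrA", 5, 25, seqlengths = g)
  expect_equal(annotate_partition(inA, part)[["A"]], 100)
  # conflicting overlapping labels are rejected
  bad <- interval_set(c("chrA", "chrA"), c(0, 25), c(50, 75),
                      label = c("A", "B"), seqlengths = g)
  expect_error(annotate_partition(sites, bad), "conflicting")
  # residual bases fall into "other"; totals are conserved on random cases
  set.seed(29)
  for (i in 1:10) {
    g2 <- c(c1 = 400, c2 = 300)
    cut1 <- sort(sample(50:350, 2))
    part2 <- interval_set(c("c1", "c1", "c2"), c(0, cut1[1], 0),
                          c(cut1[1], cut1[2], 120),
                          label = c("x", "y", "x"), seqlengths = g2)
    s2 <- random_interval_set(6, g2)
    pc2 <- annotate_partition(s2, part2)
    expect_equal(sum(pc2), 100)
    expect_equal(pc2[sort(names(pc2))],
                 oracle_annotate(s2, part2)[sort(names(pc2))])
  }
})

test_that("gene-model partition follows the documented precedence", {
  g <- c(chrA = 10000)
  genes <- data.frame(chrom = "chrA", start = 3000, end = 6000, strand = "+",
                      thick_start = 3500, thick_end = 5500,
                      block_sizes = "600,1000", block_starts = "0,2000",
                      stringsAsFactors = FALSE)
  part <- gene_model_partition(genes, g, tss_window = 1000)
  lab_at <- function(pos) {
    d <- part$intervals
    d$label[d$start <= pos & pos < d$end]
  }
  expect_equal(lab_at(2500), "tss")       # inside the +/-1kb TSS window
  expect_equal(lab_at(3400), "tss")       # TSS window wins over UTR
  expect_equal(lab_at(4500), "intron")    # between blocks, inside span
  expect_equal(lab_at(5200), "exon")      # second block, inside CDS
  expect_equal(lab_at(5700), "utr")       # exonic beyond CDS end
  expect_equal(lab_at(8000), "intergenic")
  # the partition tiles the genome exactly once
  expect_equal(covered_bases(part), sum(g))
  expect_equal(sum(with(part$intervals, end - start)), sum(g))
})

test_that("BED and chromosome sizes round-trip", {
  x <- interval_set(c("chrA", "chrB"), c(0, 10), c(100, 60),
                    label = c("s1", "s2"), seqlengths = toy_genome)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, bed)
  back <- read_bed(bed, seqlengths = toy_genome)
  expect_equal(back$intervals, x$intervals)
  sizes <- withr::local_tempfile(fileext = ".tsv")
  write_chrom_sizes(toy_genome, sizes)
  expect_equal(read_chrom_sizes(sizes), toy_genome)
})

test_that("a full correlation report renders floor p-values honestly", {
  iv <- sim_intervals(simulation_spec(seed = 2, n_intervals = 60L))
  rep_ <- interval_correlation(iv$query, iv$reference, n_perm = 19, seed = 1)
  expect_s3_class(rep_, "correlation_report")
  expect_true(all(c("jaccard", "projection_p", "area_permutation_p",
                    "relative_ecdf_area_correlation") %in% names(rep_)))
  out <- capture.output(print(rep_))
  expect_true(any(grepl("permutations, seed", out)))
  expect_false(any(grepl("p 0($| )", out)))  # a permutation p is never "0"
})
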