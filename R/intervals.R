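#' Genomic interval sets
#'
#' An `interval_set` holds per-chromosome sorted half-open 0-based intervals
#' (BED convention), optionally labeled, together with chromosome lengths.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; intervals are `[start, end)` with
#'   `0 <= start < end <= seqlengths[chrom]`.
#' @param label optional per-interval labels.
#' @param seqlengths named vector of chromosome lengths; when `NULL` it is
#'   inferred as the maximal end per chromosome.
#' @return an object of class `interval_set`.
#' @export
interval_set <- function(chrom, start, end, label = NULL, seqlengths = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- max(length(chrom), length(start), length(end))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(start, n)
  end <- rep_len(end, n)
  if (!is.null(label)) label <- rep_len(as.character(label), n)
  bad <- which(start >= end | start < 0)
  if (length(bad))
    stop("invalid interval(s) (need 0 <= start < end) at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  if (is.null(seqlengths)) {
    seqlengths <- tapply(end, chrom, max)
    seqlengths <- setNames(as.numeric(seqlengths), names(seqlengths))
  }
  missing_chr <- setdiff(unique(chrom), names(seqlengths))
  if (length(missing_chr))
    stop("chromosome(s) absent from seqlengths: ",
         paste(missing_chr, collapse = ", "))
  over <- which(end > seqlengths[chrom])
  if (length(over))
    stop("interval(s) beyond chromosome end at row(s): ",
         paste(head(over, 5), collapse = ", "))
  df <- data.frame(chrom = chrom, start = start, end = end,
                   label = if (is.null(label)) rep(NA_character_, n)
                           else label,
                   stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(intervals = df, seqlengths = seqlengths),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d intervals on %d chromosome(s), %s bases covered\n",
              nrow(x$intervals), length(unique(x$intervals$chrom)),
              format(sum(x$intervals$end - x$intervals$start), big.mark = ",")))
  invisible(x)
}

#' Number of intervals and covered bases
#' @param x an `interval_set`.
#' @return `n_intervals()`: integer; `covered_bases()`: numeric (bases after
#'   merging).
#' @export
n_intervals <- function(x) nrow(x$intervals)

#' @rdname n_intervals
#' @export
covered_bases <- function(x) {
  m <- merge_intervals(x)
  sum(m$intervals$end - m$intervals$start)
}

iranges_of <- function(x, chr) {
  d <- x$intervals[x$intervals$chrom == chr, , drop = FALSE]
  IRanges::IRanges(start = d$start + 1L, end = d$end)  # 1-based closed
}

set_from_chrlist <- function(lst, seqlengths) {
  # lst: named list chrom -> IRanges
  chrom <- rep(names(lst), vapply(lst, length, integer(1)))
  if (!length(chrom))
    return(structure(list(intervals = data.frame(chrom = character(),
                                                 start = numeric(),
                                                 end = numeric(),
                                                 label = character(),
                                                 stringsAsFactors = FALSE),
                          seqlengths = seqlengths),
                     class = "interval_set"))
  st <- unlist(lapply(lst, IRanges::start), use.names = FALSE) - 1
  en <- unlist(lapply(lst, IRanges::end), use.names = FALSE)
  interval_set(chrom, st, en, seqlengths = seqlengths)
}

#' Merge overlapping (and by default adjacent) intervals
#'
#' Unions overlapping intervals per chromosome; with `adjacent = TRUE`
#' (default) book-ended intervals such as `[0,10)` and `[10,20)` merge too.
#' Total covered bases are preserved.
#'
#' @param x an `interval_set`.
#' @param adjacent merge book-ended intervals (default `TRUE`).
#' @return a merged `interval_set` (labels are dropped).
#' @export
merge_intervals <- function(x, adjacent = TRUE) {
  chrs <- unique(x$intervals$chrom)
  lst <- lapply(setNames(chrs, chrs), function(chr)
    IRanges::reduce(iranges_of(x, chr),
                    min.gapwidth = if (adjacent) 1L else 0L))
  set_from_chrlist(lst, x$seqlengths)
}

#' Base-exact intersection of two interval sets
#'
#' @param a,b `interval_set`s (merged or not).
#' @return the `interval_set` of bases covered by both.
#' @export
intersect_intervals <- function(a, b) {
  chrs <- intersect(unique(a$intervals$chrom), unique(b$intervals$chrom))
  lst <- lapply(setNames(chrs, chrs), function(chr)
    IRanges::intersect(iranges_of(a, chr), iranges_of(b, chr)))
  seql <- a$seqlengths
  add <- setdiff(names(b$seqlengths), names(seql))
  if (length(add)) seql <- c(seql, b$seqlengths[add])
  set_from_chrlist(lst, seql)
}

union_bases <- function(a, b) {
  chrs <- union(unique(a$intervals$chrom), unique(b$intervals$chrom))
  sum(vapply(chrs, function(chr)
    sum(IRanges::width(IRanges::reduce(c(iranges_of(a, chr),
                                         iranges_of(b, chr))))),
    numeric(1)))
}

intersection_bases <- function(a, b) {
  s <- intersect_intervals(a, b)
  sum(s$intervals$end - s$intervals$start)
}

#' Coverage of query intervals by a reference set
#'
#' For every query interval, the fraction of its bases overlapped by the
#' (merged) reference set, plus a per-chromosome five-number summary of
#' those fractions.  Chromosomes absent from the reference yield fractions
#' of 0.
#'
#' @param query,reference `interval_set`s.
#' @return list with `per_interval` (data frame `chrom`, `start`, `end`,
#'   `fraction`) and `per_chrom` (data frame `chrom`, `min`, `q1`, `median`,
#'   `q3`, `max`, `n`).
#' @export
coverage_fraction <- function(query, reference) {
  ref <- merge_intervals(reference)
  d <- query$intervals
  frac <- numeric(nrow(d))
  for (chr in unique(d$chrom)) {
    qi <- which(d$chrom == chr)
    qr <- IRanges::IRanges(d$start[qi] + 1L, d$end[qi])
    rr <- iranges_of(ref, chr)
    if (length(rr) == 0L) next
    ov <- IRanges::findOverlaps(qr, rr)
    if (length(ov) == 0L) next
    w <- IRanges::width(IRanges::pintersect(qr[S4Vectors::queryHits(ov)],
                                            rr[S4Vectors::subjectHits(ov)]))
    cov <- tapply(w, S4Vectors::queryHits(ov), sum)
    frac[qi[as.integer(names(cov))]] <- as.numeric(cov)
  }
  frac <- frac / (d$end - d$start)
  per_chrom <- do.call(rbind, lapply(unique(d$chrom), function(chr) {
    f <- frac[d$chrom == chr]
    fv <- fivenum(f)
    data.frame(chrom = chr, min = fv[1], q1 = fv[2], median = fv[3],
               q3 = fv[4], max = fv[5], n = length(f),
               stringsAsFactors = FALSE)
  }))
  list(per_interval = data.frame(d[, c("chrom", "start", "end")],
                                 fraction = frac, stringsAsFactors = FALSE),
       per_chrom = per_chrom)
}

# run expr under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

# relocation null: place each interval uniformly within its chromosome,
# preserving per-chromosome interval counts and lengths; overlap allowed
relocate_intervals <- function(x) {
  d <- x$intervals
  len <- x$seqlengths[d$chrom]
  w <- d$end - d$start
  maxs <- pmax(len - w, 0)
  ns <- floor(runif(nrow(d)) * (maxs + 1))
  ns <- pmin(ns, maxs)
  interval_set(d$chrom, ns, ns + w, seqlengths = x$seqlengths)
}

#' Jaccard statistic with a relocation permutation test
#'
#' `jaccard_index()` is intersecting bases over union bases of the two
#' merged sets.  `jaccard_test()` additionally draws a null by relocating
#' `a`'s intervals uniformly and independently within each chromosome
#' (counts and lengths preserved, overlap allowed) and reports
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param a,b `interval_set`s sharing a chromosome-length map.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed (mandatory in reports).
#' @return `jaccard_test()`: list with `value`, `p_value`, `n_perm`, `seed`.
#'   An empty union yields `value = NA` with a warning.
#' @export
jaccard_index <- function(a, b) {
  u <- union_bases(a, b)
  if (u == 0) {
    warning("empty union; Jaccard undefined")
    return(NA_real_)
  }
  intersection_bases(a, b) / u
}

#' @rdname jaccard_index
#' @export
jaccard_test <- function(a, b, n_perm = 999L, seed = 1L) {
  a <- merge_intervals(a)
  b <- merge_intervals(b)
  obs <- jaccard_index(a, b)
  nulls <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    jaccard_index(merge_intervals(relocate_intervals(a)), b), numeric(1)))
  list(value = obs,
       p_value = (1 + sum(nulls >= obs)) / (1 + n_perm),
       n_perm = n_perm, seed = seed)
}

midpoints_df <- function(x) {
  d <- x$intervals
  data.frame(chrom = d$chrom, pos = floor((d$start + d$end) / 2),
             stringsAsFactors = FALSE)
}

#' Projection test
#'
#' Counts how many query interval midpoints fall inside the (merged)
#' reference set and compares against a binomial with success rate equal to
#' the reference's covered fraction of the mappable genome (the full length
#' of the chromosomes carrying query intervals, unless a mask is supplied as
#' `mappable`).  Two-sided: twice the smaller binomial tail, capped at 1.
#'
#' @param query,reference `interval_set`s.
#' @param mappable optional named vector of mappable lengths per chromosome.
#' @return list with `p_value`, `k` (midpoints inside), `n` (midpoints),
#'   `coverage` (binomial rate).
#' @export
projection_test <- function(query, reference, mappable = NULL) {
  ref <- merge_intervals(reference)
  mids <- midpoints_df(query)
  chrs <- unique(mids$chrom)
  if (is.null(mappable)) mappable <- query$seqlengths[chrs]
  genome_len <- sum(mappable)
  if (genome_len <= 0) stop("zero-length genome")
  rd <- ref$intervals[ref$intervals$chrom %in% chrs, , drop = FALSE]
  c_rate <- sum(rd$end - rd$start) / genome_len
  inside <- logical(nrow(mids))
  for (chr in chrs) {
    qi <- which(mids$chrom == chr)
    rr <- rd[rd$chrom == chr, , drop = FALSE]
    if (!nrow(rr)) next
    idx <- findInterval(mids$pos[qi], rr$start)
    inside[qi] <- idx >= 1 & mids$pos[qi] < rr$end[pmax(idx, 1)]
  }
  k <- sum(inside)
  n <- nrow(mids)
  lower <- pbinom(k, n, c_rate)
  upper <- pbinom(k - 1, n, c_rate, lower.tail = FALSE)
  list(p_value = min(1, 2 * min(lower, upper)), k = k, n = n,
       coverage = c_rate)
}

rel_abs_distances <- function(query, reference) {
  qm <- midpoints_df(merge_intervals(query))
  rm_ <- midpoints_df(merge_intervals(reference))
  rel <- numeric(0)
  absd <- numeric(0)
  skipped <- character(0)
  for (chr in unique(qm$chrom)) {
    q <- sort(qm$pos[qm$chrom == chr])
    r <- sort(rm_$pos[rm_$chrom == chr])
    if (length(r) < 2L) {
      skipped <- c(skipped, chr)
      next
    }
    # absolute: distance to the nearest reference midpoint
    i <- findInterval(q, r)
    left <- r[pmax(i, 1L)]
    right <- r[pmin(i + 1L, length(r))]
    absd <- c(absd, pmin(abs(q - left), abs(q - right)))
    # relative: only midpoints strictly inside the flanked span
    inb <- i >= 1L & i < length(r)
    qi <- q[inb]
    lo <- r[i[inb]]
    hi <- r[i[inb] + 1L]
    gap <- hi - lo
    d <- ifelse(gap == 0, 0, pmin(qi - lo, hi - qi) / gap)
    rel <- c(rel, d)
  }
  list(relative = rel, absolute = absd, skipped = skipped)
}

#' Midpoint-distance correlation statistics
#'
#' Computes, for each query interval midpoint, (i) the relative distance to
#' the nearest flanking reference midpoint scaled by the flanking gap
#' (uniform on `[0, 0.5]` under independence) and (ii) the absolute distance
#' to the nearest reference midpoint.  Reports a Kolmogorov-Smirnov test of
#' the relative distances against Uniform(0, 0.5); the relative ECDF area
#' correlation `(integral of [ECDF(d) - 2 d] over [0, 0.5]) / 0.25`, which
#' is 1 for coinciding point sets and about 0 under independence; a KS test
#' of the absolute distances against pooled relocation-null distances; and
#' an ECDF-area permutation test of the absolute distances against
#' relocation nulls.  Chromosomes with fewer than 2 reference midpoints are
#' skipped with a notice.
#'
#' @param query,reference `interval_set`s.
#' @param n_perm permutations for the relocation null (default 999).
#' @param seed RNG seed.
#' @return list with `ks_p_relative`, `ks_p_absolute`,
#'   `area_permutation_p`, `relative_ecdf_area_correlation`, `n_points`,
#'   `skipped_chroms`, `n_perm`, `seed`.
#' @export
distance_correlation <- function(query, reference, n_perm = 999L, seed = 1L) {
  obs <- rel_abs_distances(query, reference)
  if (length(obs$relative) == 0L)
    stop("no usable query midpoints (every chromosome skipped?)")
  area_corr <- 1 - 4 * mean(obs$relative)
  ks_rel <- suppressWarnings(
    ks.test(obs$relative, "punif", min = 0, max = 0.5))$p.value
  qm <- merge_intervals(query)
  null_means <- numeric(n_perm)
  null_pool <- vector("list", min(n_perm, 50L))
  with_seed(seed, for (i in seq_len(n_perm)) {
    nd <- rel_abs_distances(relocate_intervals(qm), reference)
    null_means[i] <- mean(nd$absolute)
    if (i <= length(null_pool)) null_pool[[i]] <- nd$absolute
  })
  # larger ECDF area over [0, D] <=> smaller mean absolute distance
  p_area <- (1 + sum(null_means <= mean(obs$absolute))) / (1 + n_perm)
  ks_abs <- suppressWarnings(
    ks.test(obs$absolute, unlist(null_pool)))$p.value
  list(ks_p_relative = ks_rel,
       ks_p_absolute = ks_abs,
       area_permutation_p = p_area,
       relative_ecdf_area_correlation = area_corr,
       n_points = length(obs$relative),
       skipped_chroms = obs$skipped,
       n_perm = n_perm, seed = seed)
}

#' Full interval correlation report
#'
#' Bundles the Jaccard permutation test, the projection test and the
#' absolute/relative midpoint-distance statistics into one report.  In the
#' printed report a permutation p-value at its floor is rendered as
#' `< 1/(n_perm + 1)` -- a permutation test never certifies an exact zero.
#'
#' @inheritParams jaccard_test
#' @param query,reference `interval_set`s.
#' @return an object of class `correlation_report` (a list).
#' @export
interval_correlation <- function(query, reference, n_perm = 999L, seed = 1L) {
  q <- merge_intervals(query)
  r <- merge_intervals(reference)
  jt <- jaccard_test(q, r, n_perm = n_perm, seed = seed)
  pt <- projection_test(q, r)
  dc <- distance_correlation(q, r, n_perm = n_perm, seed = seed + 1L)
  structure(list(jaccard = jt$value, jaccard_p = jt$p_value,
                 projection_p = pt$p_value,
                 ks_p_relative = dc$ks_p_relative,
                 ks_p_absolute = dc$ks_p_absolute,
                 area_permutation_p = dc$area_permutation_p,
                 relative_ecdf_area_correlation = dc$relative_ecdf_area_correlation,
                 n_perm = n_perm, seed = seed),
            class = "correlation_report")
}

format_pval <- function(p, n_perm) {
  floor_p <- 1 / (n_perm + 1)
  if (is.na(p)) "NA" else if (p <= floor_p) sprintf("< %.4g", floor_p)
  else sprintf("%.4g", p)
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report>  (", x$n_perm, "permutations, seed", x$seed, ")\n")
  cat(sprintf("  Jaccard                     %.4f  (p %s)\n",
              x$jaccard, format_pval(x$jaccard_p, x$n_perm)))
  cat(sprintf("  projection test p           %s\n",
              format_pval(x$projection_p, x$n_perm)))
  cat(sprintf("  KS p (relative distance)    %s\n",
              format_pval(x$ks_p_relative, x$n_perm)))
  cat(sprintf("  KS p (absolute distance)    %s\n",
              format_pval(x$ks_p_absolute, x$n_perm)))
  cat(sprintf("  area permutation p          %s\n",
              format_pval(x$area_permutation_p, x$n_perm)))
  cat(sprintf("  relative ECDF area corr.    %.3f\n",
              x$relative_ecdf_area_correlation))
  invisible(x)
}

#' Annotate sites against a labeled genome partition
#'
#' Distributes the bases of `sites` over the labels of `partition` and
#' returns the percentage of site bases per label; bases covered by no
#' partition label are reported under `other_label`.  Partition intervals
#' with conflicting labels overlapping each other are rejected (a partition
#' must be a partition).  Percentages sum to 100 up to rounding.
#'
#' @param sites an `interval_set`.
#' @param partition a labeled `interval_set`.
#' @param other_label label for uncovered residual bases.
#' @return named numeric vector of percentages.
#' @export
annotate_partition <- function(sites, partition, other_label = "other") {
  labs <- partition$intervals$label
  if (anyNA(labs)) stop("partition intervals must all be labeled")
  by_lab <- lapply(split(seq_len(nrow(partition$intervals)), labs), function(i) {
    d <- partition$intervals[i, , drop = FALSE]
    merge_intervals(interval_set(d$chrom, d$start, d$end,
                                 seqlengths = partition$seqlengths))
  })
  tot_by_lab <- vapply(by_lab, covered_bases, numeric(1))
  merged_all <- merge_intervals(partition)
  if (sum(tot_by_lab) > covered_bases(merged_all) + 1e-9)
    stop("overlapping partition intervals with conflicting labels")
  s <- merge_intervals(sites)
  total <- covered_bases(s)
  if (total == 0) stop("sites cover zero bases")
  bases <- vapply(by_lab, function(p) intersection_bases(s, p), numeric(1))
  res <- bases
  other <- total - sum(bases)
  if (other > 0 || other_label %in% names(res)) {
    res[other_label] <- if (other_label %in% names(res))
      res[other_label] + max(other, 0) else max(other, 0)
  }
  100 * res / total
}

#' Fraction of sites intersecting at least one feature
#'
#' @param sites,features `interval_set`s (merged internally).
#' @return the count of site intervals with at least one overlapping base in
#'   `features`, divided by the number of sites; `NA` with a warning when
#'   there are no sites.
#' @export
site_overlap_fraction <- function(sites, features) {
  s <- merge_intervals(sites)
  f <- merge_intervals(features)
  n <- nrow(s$intervals)
  if (n == 0L) {
    warning("zero sites; overlap fraction undefined")
    return(NA_real_)
  }
  hit <- 0L
  for (chr in unique(s$intervals$chrom)) {
    ov <- IRanges::countOverlaps(iranges_of(s, chr), iranges_of(f, chr))
    hit <- hit + sum(ov > 0)
  }
  hit / n
}

#' Gene-model genome partition
#'
#' Builds a labeled partition of the genome from transcript models with the
#' CEAS-like precedence TSS window > UTR > exon > intron > intergenic: a
#' window of `tss_window` bases either side of each transcription start
#' site; untranslated exonic bases (requires `thick_start`/`thick_end` CDS
#' columns); remaining exonic bases; remaining transcript-span bases; and
#' everything else.
#'
#' @param genes data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open transcript span), `strand` (`"+"`/`"-"`), and optionally
#'   `thick_start`, `thick_end` (CDS span) and `block_sizes`,
#'   `block_starts` (BED12-style comma-joined exon blocks relative to
#'   `start`).
#' @param seqlengths named chromosome-length vector.
#' @param tss_window half-width of the TSS-proximal window in bases
#'   (default 1000).
#' @return a labeled `interval_set` partitioning the genome into
#'   `tss`, `utr`, `exon`, `intron`, `intergenic`.
#' @export
gene_model_partition <- function(genes, seqlengths, tss_window = 1000) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(genes)))
  clip_set <- function(chrom, start, end) {
    keep <- start < end
    interval_set(chrom[keep], pmax(start[keep], 0),
                 pmin(end[keep], seqlengths[chrom[keep]]),
                 seqlengths = seqlengths)
  }
  tss_pos <- ifelse(genes$strand == "-", genes$end - 1, genes$start)
  tss <- clip_set(genes$chrom, tss_pos - tss_window, tss_pos + tss_window)
  # exon blocks
  if (all(c("block_sizes", "block_starts") %in% names(genes))) {
    bs <- lapply(strsplit(as.character(genes$block_sizes), ","), as.numeric)
    bo <- lapply(strsplit(as.character(genes$block_starts), ","), as.numeric)
    ex_chrom <- rep(genes$chrom, lengths(bs))
    ex_start <- rep(genes$start, lengths(bs)) + unlist(bo)
    ex_end <- ex_start + unlist(bs)
  } else {
    ex_chrom <- genes$chrom
    ex_start <- genes$start
    ex_end <- genes$end
  }
  exons <- clip_set(ex_chrom, ex_start, ex_end)
  span <- clip_set(genes$chrom, genes$start, genes$end)
  if (all(c("thick_start", "thick_end") %in% names(genes))) {
    cds <- clip_set(genes$chrom, genes$thick_start, genes$thick_end)
    utr <- setdiff_intervals(exons, cds)
  } else {
    utr <- interval_set(character(), numeric(), numeric(),
                        seqlengths = seqlengths)
  }
  genome <- interval_set(names(seqlengths), rep(0, length(seqlengths)),
                         seqlengths, seqlengths = seqlengths)
  pieces <- list(tss = merge_intervals(tss), utr = utr, exon = exons,
                 intron = span, intergenic = genome)
  assigned <- interval_set(character(), numeric(), numeric(),
                           seqlengths = seqlengths)
  out <- NULL
  for (lab in names(pieces)) {
    piece <- setdiff_intervals(pieces[[lab]], assigned)
    if (nrow(piece$intervals)) {
      d <- piece$intervals
      d$label <- lab
      out <- rbind(out, d)
      assigned <- merge_intervals(interval_set(
        c(assigned$intervals$chrom, d$chrom),
        c(assigned$intervals$start, d$start),
        c(assigned$intervals$end, d$end), seqlengths = seqlengths))
    }
  }
  interval_set(out$chrom, out$start, out$end, label = out$label,
               seqlengths = seqlengths)
}

#' Base-wise set difference of two interval sets
#'
#' @param a,b `interval_set`s.
#' @return bases of `a` not in `b`, merged.
#' @export
setdiff_intervals <- function(a, b) {
  chrs <- unique(a$intervals$chrom)
  lst <- lapply(setNames(chrs, chrs), function(chr)
    IRanges::setdiff(iranges_of(a, chr), iranges_of(b, chr)))
  set_from_chrlist(lst, a$seqlengths)
}

#' BED and chromosome-sizes input/output
#'
#' BED (3- or 4-column; the 4th column becomes the interval label) via
#' rtracklayer, converting between BED's 0-based half-open convention and
#' the `interval_set` representation.  Chromosome sizes are a two-column
#' headerless TSV (`chrom`, `length`).
#'
#' @param path file path.
#' @param seqlengths optional chromosome lengths applied on read.
#' @param x an `interval_set` to write.
#' @return `read_bed()` / `read_chrom_sizes()`: the parsed object;
#'   writers return `path` invisibly.
#' @export
read_bed <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  lab <- if (!is.null(gr$name)) gr$name else NULL
  interval_set(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
               label = lab, seqlengths = seqlengths)
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  d <- x$intervals
  gr <- GenomicRanges::GRanges(d$chrom,
                               IRanges::IRanges(d$start + 1L, d$end))
  if (!all(is.na(d$label))) gr$name <- d$label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' @rdname read_bed
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  setNames(as.numeric(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_bed
#' @param sizes named chromosome-length vector to write.
#' @export
write_chrom_sizes <- function(sizes, path) {
  write.table(data.frame(names(sizes), as.numeric(sizes)), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
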