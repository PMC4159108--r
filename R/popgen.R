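## Diversity and differentiation statistics: allele frequencies, Watterson's
## theta, population-specific allele detection, Weir-Cockerham F_ST (weighted,
## small-sample corrected, allele-frequency form on chromosomes), empirical
## percentile outlier calling, and the Welch test on per-individual dosages.

#' Group-wise alternate-allele frequencies
#'
#' Frequencies are alt chromosomes / called chromosomes within each group;
#' missing genotypes are excluded from the denominator. A group with zero
#' called chromosomes at a variant gets frequency `NA`.
#'
#' @param vt a [variant_table()]
#' @param grouping `"population"`, `"region"`, or `"pooled"` (Africa vs
#'   non-Africa; admixed samples contribute to neither pool)
#' @param africa_label region label identifying the African pool (default
#'   `"Africa"`)
#' @return list with matrices `freq` and `n_chrom` (groups x variants) and the
#'   group -> sample assignment `groups`
#' @export
allele_frequencies <- function(vt, grouping = c("population", "region", "pooled"),
                               africa_label = "Africa") {
  grouping <- match.arg(grouping)
  panel <- vt$panel
  groups <- switch(grouping,
    population = split(panel$sample_id, panel$population),
    region = split(panel$sample_id, panel$region),
    pooled = {
      keep <- !panel$admixed
      split(panel$sample_id[keep],
            ifelse(panel$region[keep] == africa_label, africa_label,
                   paste0("non-", africa_label)))
    })
  freq <- matrix(NA_real_, length(groups), nrow(vt$variants),
                 dimnames = list(names(groups), variant_key(vt)))
  n_chrom <- matrix(0L, length(groups), nrow(vt$variants),
                    dimnames = dimnames(freq))
  for (g in names(groups)) {
    sub <- vt$geno[, groups[[g]], drop = FALSE]
    called <- 2L * rowSums(!is.na(sub))
    alt <- rowSums(sub, na.rm = TRUE)
    freq[g, ] <- ifelse(called > 0, alt / called, NA_real_)
    n_chrom[g, ] <- called
  }
  list(freq = freq, n_chrom = n_chrom, groups = groups)
}

#' Watterson's estimator of the population mutation rate per site
#'
#' theta_W = S / (a_n * L) with a_n the (n-1)-th harmonic number
#' Sum_{i=1}^{n-1} 1/i, S the number of segregating sites among n sampled
#' chromosomes and L the surveyed length in bases.
#'
#' @param S segregating-site count (>= 0)
#' @param n number of chromosomes (>= 2)
#' @param L surveyed bases (> 0)
#' @param group,sequence_class optional labels carried into the result
#' @return one-row data.frame: group, sequence_class, S, n, L, a_n,
#'   theta_per_site
#' @export
watterson_theta <- function(S, n, L, group = NA_character_,
                            sequence_class = NA_character_) {
  if (n < 2) stop("watterson_theta needs n >= 2 chromosomes")
  if (L <= 0) stop("watterson_theta needs L > 0 surveyed bases")
  if (S < 0) stop("S must be >= 0")
  a_n <- sum(1 / seq_len(n - 1))
  data.frame(group = group, sequence_class = sequence_class,
             S = S, n = n, L = L, a_n = a_n,
             theta_per_site = S / (a_n * L), stringsAsFactors = FALSE)
}

#' Watterson's theta per group and sequence class
#'
#' Counts segregating sites within each group (population or region) for each
#' region class and divides by that class's total bases in the catalog.
#' The chromosome count n per group is the median called chromosome count
#' across its variants (2 x individuals when no genotypes are missing).
#'
#' @param vt a [variant_table()]
#' @param annotated output of [classify_variants()]
#' @param catalog a [mirna_catalog()]
#' @param grouping `"population"` or `"region"`
#' @return data.frame of [watterson_theta()] rows
#' @export
theta_by_class <- function(vt, annotated, catalog,
                           grouping = c("population", "region")) {
  grouping <- match.arg(grouping)
  af <- allele_frequencies(vt, grouping)
  bases <- region_base_counts(catalog)
  ann <- annotated[annotated$region != "none", , drop = FALSE]
  ann <- ann[!duplicated(ann[, c("record", "region")]), , drop = FALSE]
  out <- list()
  for (g in rownames(af$freq)) {
    n_g <- 2L * length(af$groups[[g]])
    for (rc in names(bases)) {
      recs <- ann$record[ann$region == rc]
      f <- af$freq[g, recs]
      S <- sum(f > 0 & f < 1, na.rm = TRUE)
      out[[length(out) + 1L]] <-
        watterson_theta(S, n_g, bases[[rc]], group = g, sequence_class = rc)
    }
  }
  do.call(rbind, out)
}

#' Detect population-specific miRNA alleles (PSMAs)
#'
#' A PSMA is an alternate allele observed (frequency > 0) in exactly one of the
#' sampled populations. High-frequency PSMAs have within-population frequency
#' >= `high_freq`. Per-population density divides the PSMA count by the number
#' of genomes sampled for that population.
#'
#' @param vt a [variant_table()]
#' @param high_freq high-frequency threshold (default 0.5, i.e. >= 50%)
#' @return list with `records` (variant_key, population, freq, high_frequency)
#'   and `density` (population, n_psma, n_genomes, density)
#' @export
detect_psma <- function(vt, high_freq = 0.5) {
  af <- allele_frequencies(vt, "population")
  present <- af$freq > 0 & !is.na(af$freq)
  n_pops_present <- colSums(present)
  is_psma <- n_pops_present == 1L
  pop <- rownames(af$freq)[apply(present, 2, function(z) which(z)[1])]
  keys <- colnames(af$freq)
  recs <- data.frame(
    variant_key = keys[is_psma],
    population = pop[is_psma],
    freq = af$freq[cbind(pop[is_psma], keys[is_psma])],
    stringsAsFactors = FALSE)
  recs$high_frequency <- recs$freq >= high_freq
  ng <- n_genomes(vt$panel)
  dens <- data.frame(
    population = names(ng),
    n_psma = vapply(names(ng), function(p) sum(recs$population == p), integer(1)),
    n_genomes = as.integer(ng), row.names = NULL, stringsAsFactors = FALSE)
  dens$density <- dens$n_psma / dens$n_genomes
  list(records = recs, density = dens)
}

#' Weir-Cockerham F_ST between two groups (allele-frequency form)
#'
#' Weighted estimator with small-sample correction, in the haploid-sample form:
#' the 2N chromosomes of each group are the sample and the per-chromosome
#' allele indicator the observation. With r = 2 groups, sample sizes n1, n2
#' (chromosomes) and alt frequencies p1, p2:
#' n_bar = (n1+n2)/2, n_c = (n1+n2 - (n1^2+n2^2)/(n1+n2))/(r-1),
#' p_bar = weighted mean, s2 = sum n_i (p_i - p_bar)^2 / ((r-1) n_bar);
#' a = (n_bar/n_c) * (s2 - (p_bar(1-p_bar) - s2 (r-1)/r) / (n_bar-1)),
#' w = (n_bar/(n_bar-1)) * (p_bar(1-p_bar) - s2 (r-1)/r),
#' theta_hat = a/(a+w). When both groups are monomorphic for the same allele
#' the estimator is undefined (`defined = FALSE`, theta `NA`). Negative
#' theta_hat is truncated to 0 in `theta_reported`; the raw value is kept.
#'
#' All arguments vectorise over variants.
#'
#' @param p1,p2 alt-allele frequencies in each group
#' @param n1,n2 called chromosome counts in each group (>= 2)
#' @return data.frame: p1, n1, p2, n2, a, w, theta_raw, theta_reported,
#'   defined
#' @export
wc_fst <- function(p1, n1, p2, n2) {
  if (any(stats::na.omit(c(n1, n2)) < 2))
    stop("wc_fst needs >= 2 chromosomes per group")
  r <- 2
  n_tot <- n1 + n2
  n_bar <- n_tot / r
  n_c <- (n_tot - (n1^2 + n2^2) / n_tot) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / n_tot
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  inner <- p_bar * (1 - p_bar) - s2 * (r - 1) / r
  a <- (n_bar / n_c) * (s2 - inner / (n_bar - 1))
  w <- (n_bar / (n_bar - 1)) * inner
  denom <- a + w
  defined <- is.finite(p1) & is.finite(p2) & abs(denom) > .Machine$double.eps^0.75
  theta_raw <- ifelse(defined, a / denom, NA_real_)
  data.frame(p1 = p1, n1 = n1, p2 = p2, n2 = n2, a = a, w = w,
             theta_raw = theta_raw,
             theta_reported = pmax(theta_raw, 0),
             defined = defined)
}

#' Welch two-sided t-test on per-individual alt dosages
#'
#' Dosages are alternate-allele counts / ploidy (0, 0.5, 1 per diploid);
#' missing genotypes are excluded. Vectorises over variants when given
#' matrices (variants x samples). Degenerate cases: both groups zero-variance
#' with equal means gives t = 0, p = 1; with different means p = 0 and
#' `degenerate = TRUE`.
#'
#' @param dosagesA,dosagesB numeric vectors (one variant) or matrices
#'   (variants x samples) of per-individual dosages
#' @return data.frame: t, df, p, nA, nB, degenerate
#' @export
welch_test <- function(dosagesA, dosagesB) {
  if (is.null(dim(dosagesA))) dosagesA <- matrix(dosagesA, nrow = 1)
  if (is.null(dim(dosagesB))) dosagesB <- matrix(dosagesB, nrow = 1)
  nA <- rowSums(!is.na(dosagesA)); nB <- rowSums(!is.na(dosagesB))
  if (any(nA < 2) || any(nB < 2))
    stop("welch_test needs >= 2 non-missing individuals per group")
  mA <- rowMeans(dosagesA, na.rm = TRUE); mB <- rowMeans(dosagesB, na.rm = TRUE)
  vA <- rowSums((dosagesA - mA)^2, na.rm = TRUE) / (nA - 1)
  vB <- rowSums((dosagesB - mB)^2, na.rm = TRUE) / (nB - 1)
  se2 <- vA / nA + vB / nB
  zero <- se2 == 0
  t <- ifelse(zero, ifelse(mA == mB, 0, sign(mA - mB) * Inf),
              (mA - mB) / sqrt(se2))
  df <- ifelse(zero, NA_real_,
               se2^2 / (vA^2 / (nA^2 * (nA - 1)) + vB^2 / (nB^2 * (nB - 1))))
  p <- ifelse(zero, ifelse(mA == mB, 1, 0), 2 * pt(-abs(t), df))
  data.frame(t = t, df = df, p = p, nA = nA, nB = nB,
             degenerate = zero & mA != mB)
}

#' Enumerate the hierarchical contrasts of a panel
#'
#' All population pairs, all region pairs, and the pooled Africa vs non-Africa
#' contrast (admixed samples in neither pool; the admixed "region" is excluded
#' from region pairs only when it has no non-admixed samples left).
#'
#' @param panel a [genome_panel()]
#' @param africa_label region label of the African pool
#' @return data.frame: contrast, level (population/region/pooled), groupA,
#'   groupB, plus a `samples` list-column of the two sample-id sets
#' @export
make_contrasts <- function(panel, africa_label = "Africa") {
  out <- list()
  add <- function(level, ga, gb, sa, sb) {
    if (!length(sa) || !length(sb))
      stop("contrast ", ga, " vs ", gb, " has an empty group")
    out[[length(out) + 1L]] <<- list(
      contrast = paste0(ga, "_vs_", gb), level = level,
      groupA = ga, groupB = gb, samplesA = sa, samplesB = sb)
  }
  pops <- sort(unique(panel$population))
  if (length(pops) > 1)
    for (i in seq_len(length(pops) - 1)) for (j in (i + 1):length(pops))
      add("population", pops[i], pops[j],
          panel$sample_id[panel$population == pops[i]],
          panel$sample_id[panel$population == pops[j]])
  regs <- sort(unique(panel$region))
  if (length(regs) > 1)
    for (i in seq_len(length(regs) - 1)) for (j in (i + 1):length(regs))
      add("region", regs[i], regs[j],
          panel$sample_id[panel$region == regs[i]],
          panel$sample_id[panel$region == regs[j]])
  keep <- !panel$admixed
  add("pooled", africa_label, paste0("non-", africa_label),
      panel$sample_id[keep & panel$region == africa_label],
      panel$sample_id[keep & panel$region != africa_label])
  out
}

#' Hierarchical pairwise F_ST scan
#'
#' One [wc_fst()] record per variant per contrast; the Welch test on
#' per-individual dosages is attached for pooled contrasts. Variants where a
#' contrast's estimator is undefined (both groups monomorphic for the same
#' allele) are kept with `defined = FALSE` and excluded downstream from
#' percentile computations.
#'
#' @param vt a [variant_table()]
#' @param contrasts output of [make_contrasts()] (default: built from the
#'   panel)
#' @return data.frame of F_ST records (variant_key, contrast, level, ...)
#' @export
fst_scan <- function(vt, contrasts = make_contrasts(vt$panel)) {
  keys <- variant_key(vt)
  res <- lapply(contrasts, function(ct) {
    gA <- vt$geno[, ct$samplesA, drop = FALSE]
    gB <- vt$geno[, ct$samplesB, drop = FALSE]
    nA <- 2 * rowSums(!is.na(gA)); nB <- 2 * rowSums(!is.na(gB))
    pA <- ifelse(nA > 0, rowSums(gA, na.rm = TRUE) / nA, NA_real_)
    pB <- ifelse(nB > 0, rowSums(gB, na.rm = TRUE) / nB, NA_real_)
    fst <- wc_fst(pA, pmax(nA, 2), pB, pmax(nB, 2))
    fst$defined <- fst$defined & nA >= 2 & nB >= 2
    rec <- cbind(data.frame(variant_key = keys, contrast = ct$contrast,
                            level = ct$level, stringsAsFactors = FALSE), fst)
    if (ct$level == "pooled") {
      wt <- welch_test(gA / 2, gB / 2)
      rec$t <- wt$t; rec$df <- wt$df; rec$p_welch <- wt$p
    } else {
      rec$t <- NA_real_; rec$df <- NA_real_; rec$p_welch <- NA_real_
    }
    rec
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Multi-locus Weir-Cockerham F_ST (weighted combination)
#'
#' The weighted multi-locus estimate combines loci as the ratio of summed
#' variance components, `sum(a) / sum(a + w)`, as Weir and Cockerham
#' prescribe. The naive mean of per-locus ratios is biased toward zero
#' (each locus's ratio is a noisy 1-df quantity and Jensen's inequality
#' bites); the weighted form is the estimator whose expectation matches the
#' drift parameter of the generating model.
#'
#' @param fst data.frame of [wc_fst()] records (undefined rows are skipped)
#' @return single numeric F_ST estimate
#' @export
wc_fst_global <- function(fst) {
  d <- fst[fst$defined, , drop = FALSE]
  if (!nrow(d)) stop("no defined loci to combine")
  sum(d$a) / sum(d$a + d$w)
}

#' Empirical percentile threshold
#'
#' The empirical q-quantile with linear interpolation between order statistics
#' (type-7 quantile rule).
#'
#' @param values numeric vector (undefined/NA records must be removed first)
#' @param q quantile in (0, 1)
#' @return threshold value
#' @export
percentile_threshold <- function(values, q) {
  if (q <= 0 || q >= 1) stop("q must be in (0, 1)")
  values <- values[is.finite(values)]
  if (!length(values)) stop("no defined values to take a percentile of")
  unname(quantile(values, q, type = 7))
}

#' Classify variants (and miRNAs) as PD / HPD
#'
#' A variant is population-differentiated (PD) when its pooled-contrast F_ST
#' is at or above the 95th empirical percentile with Welch p < alpha; highly
#' population-differentiated (HPD) when additionally at or above the 99th
#' percentile. Both cutpoints are inclusive. The miRNA-level label is the
#' maximum over the miRNA's variants.
#'
#' @param fst_pooled pooled-contrast rows of [fst_scan()] output
#' @param annotated output of [classify_variants()] (maps variant_key to
#'   mirna_id); pass `NULL` to skip miRNA-level labels
#' @param q95,q99 percentile levels (defaults 0.95, 0.99)
#' @param alpha Welch significance level (default 0.05)
#' @return list with `thresholds` (q95, q99 values), `variants` (variant_key,
#'   theta, p_welch, label) and `mirnas` (mirna_id, label) when `annotated`
#'   is supplied
#' @export
classify_pd <- function(fst_pooled, annotated = NULL, q95 = 0.95, q99 = 0.99,
                        alpha = 0.05) {
  def <- fst_pooled[fst_pooled$defined, , drop = FALSE]
  t95 <- percentile_threshold(def$theta_reported, q95)
  t99 <- percentile_threshold(def$theta_reported, q99)
  lab <- rep("none", nrow(fst_pooled))
  ok_p <- !is.na(fst_pooled$p_welch) & fst_pooled$p_welch < alpha
  th <- fst_pooled$theta_reported
  lab[fst_pooled$defined & ok_p & th >= t95] <- "PD"
  lab[fst_pooled$defined & ok_p & th >= t99] <- "HPD"
  variants <- data.frame(variant_key = fst_pooled$variant_key,
                         theta = th, p_welch = fst_pooled$p_welch,
                         label = lab, stringsAsFactors = FALSE)
  res <- list(thresholds = c(q95 = t95, q99 = t99), variants = variants)
  if (!is.null(annotated)) {
    ann <- annotated[!is.na(annotated$mirna_id), , drop = FALSE]
    ann$variant_key <- variant_key(ann)
    m <- merge(ann[, c("variant_key", "mirna_id")], variants,
               by = "variant_key")
    rank <- c(none = 0, PD = 1, HPD = 2)
    by_mirna <- tapply(rank[m$label], m$mirna_id, max)
    res$mirnas <- data.frame(mirna_id = names(by_mirna),
                             label = names(rank)[unname(by_mirna) + 1],
                             row.names = NULL, stringsAsFactors = FALSE)
  }
  res
}
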