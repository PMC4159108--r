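## Resampling enrichment analyses: evidence QC filter, bootstrap target-gene
## and biological-process enrichment against random miRNA sets, a plain
## hypergeometric over-representation test for genomic GO enrichment (an
## approximation of the external GOEAST tool, flagged as such in outputs),
## and the disease-association bootstrap.

with_seed <- function(seed, code) {
  # run code under a fixed RNG state without clobbering the caller's stream
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

empirical_p <- function(null_exceed, B) (1 + null_exceed) / (B + 1)

#' Filter target evidence into a validated target map
#'
#' A (miRNA, gene) pair is a validated target when the miRNA/mRNA expression
#' correlation is r < `r_threshold` (strict) in at least `min_datasets`
#' distinct datasets.
#'
#' @param evidence TargetEvidenceTable from [read_evidence()]
#' @param r_threshold correlation cutoff (default -0.5, strict `<`)
#' @param min_datasets minimum distinct supporting datasets (default 2)
#' @return list with `target_map` (named list: mirna_id -> character vector of
#'   gene_ids), `pairs` (mirna_id, gene_id, n_datasets, min_r),
#'   `n_targets` (named integer per miRNA) and `confidence` (named
#'   "high"/"low": high = at least one validated target)
#' @export
filter_evidence <- function(evidence, r_threshold = -0.5, min_datasets = 2) {
  pass <- evidence[evidence$r < r_threshold, , drop = FALSE]
  if (nrow(pass)) {
    key <- paste(pass$mirna_id, pass$gene_id, sep = "\r")
    nd <- tapply(pass$dataset_id, key, function(d) length(unique(d)))
    mr <- tapply(pass$r, key, min)
    keep <- names(nd)[nd >= min_datasets]
    parts <- strsplit(keep, "\r", fixed = TRUE)
    pairs <- data.frame(
      mirna_id = vapply(parts, `[[`, character(1), 1),
      gene_id = vapply(parts, `[[`, character(1), 2),
      n_datasets = as.integer(nd[keep]), min_r = as.numeric(mr[keep]),
      row.names = NULL, stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(mirna_id = character(), gene_id = character(),
                        n_datasets = integer(), min_r = numeric(),
                        stringsAsFactors = FALSE)
  }
  target_map <- split(pairs$gene_id, pairs$mirna_id)
  all_mirnas <- unique(evidence$mirna_id)
  n_targets <- setNames(integer(length(all_mirnas)), all_mirnas)
  n_targets[names(target_map)] <- lengths(target_map)
  list(target_map = target_map, pairs = pairs, n_targets = n_targets,
       confidence = setNames(ifelse(n_targets > 0, "high", "low"),
                             names(n_targets)))
}

## miRNA x gene logical incidence matrix over the full candidate pool
incidence_matrix <- function(target_map, catalog_ids, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(unlist(target_map, use.names = FALSE)))
  M <- matrix(FALSE, length(catalog_ids), length(genes),
              dimnames = list(catalog_ids, genes))
  for (m in intersect(names(target_map), catalog_ids))
    M[m, target_map[[m]]] <- TRUE
  M
}

check_boot_args <- function(obs_set, catalog_ids, B) {
  if (B < 1) stop("B must be >= 1")
  bad <- setdiff(obs_set, catalog_ids)
  if (length(bad))
    stop("observed miRNA(s) not in the candidate catalog: ",
         paste(bad, collapse = ", "))
  if (anyDuplicated(obs_set)) stop("obs_set contains duplicates")
}

#' Bootstrap target-gene enrichment for a miRNA set
#'
#' For each gene, the observed statistic is the number of miRNAs in `obs_set`
#' with that gene as a validated target. The null draws `length(obs_set)`
#' distinct miRNAs uniformly from the candidate catalog B times and recomputes
#' the statistic; the empirical p is (1 + #\{null >= observed\}) / (B + 1)
#' (one-sided, enrichment only). Genes with p < `alpha` are flagged enriched.
#'
#' @param obs_set character vector of observed miRNA ids (the paper's usage:
#'   the 8 HPD-miRNAs)
#' @param catalog_ids candidate pool of miRNA ids to resample from
#' @param target_map validated target map (from [filter_evidence()])
#' @param B replicate count (default 2000)
#' @param seed RNG seed
#' @param alpha flag threshold (default 0.05)
#' @param replace draw the null sets with replacement? (default FALSE: a
#'   random "set of 8 miRNA" is without replacement)
#' @return data.frame per gene: unit, observed, B, null_exceed, p_emp,
#'   enriched; attribute `seed`
#' @export
bootstrap_target_enrichment <- function(obs_set, catalog_ids, target_map,
                                        B = 2000, seed = 1, alpha = 0.05,
                                        replace = FALSE) {
  check_boot_args(obs_set, catalog_ids, B)
  M <- incidence_matrix(target_map, catalog_ids)
  obs <- colSums(M[obs_set, , drop = FALSE])
  k <- length(obs_set)
  exceed <- integer(length(obs))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- sample(nrow(M), k, replace = replace)
      exceed <- exceed + (colSums(M[idx, , drop = FALSE]) >= obs)
    }
  })
  p <- empirical_p(exceed, B)
  structure(data.frame(unit = names(obs), observed = as.integer(obs), B = B,
                       null_exceed = exceed, p_emp = p, enriched = p < alpha,
                       row.names = NULL, stringsAsFactors = FALSE),
            seed = seed)
}

#' Bootstrap biological-process enrichment for a miRNA set
#'
#' Each replicate (1) draws a random miRNA set of the observed size, (2) takes
#' the union of their validated target genes, (3) counts, per GO biological
#' process, the target genes annotated to it (`statistic = "count"`, default)
#' or simply whether the process is hit at all (`statistic = "presence"`).
#' The observed statistic uses `obs_set`; empirical p as in
#' [bootstrap_target_enrichment()].
#'
#' @inheritParams bootstrap_target_enrichment
#' @param go GO annotation list from [read_go()]
#' @param statistic `"count"` or `"presence"`
#' @return data.frame per process: unit, observed, B, null_exceed, p_emp,
#'   enriched; attribute `seed`
#' @export
bootstrap_process_enrichment <- function(obs_set, catalog_ids, target_map, go,
                                         B = 2000, seed = 1, alpha = 0.05,
                                         replace = FALSE,
                                         statistic = c("count", "presence")) {
  statistic <- match.arg(statistic)
  check_boot_args(obs_set, catalog_ids, B)
  genes <- sort(unique(c(unlist(target_map, use.names = FALSE),
                         go$annotations$gene_id)))
  M <- incidence_matrix(target_map, catalog_ids, genes)
  procs <- sort(unique(go$annotations$process_id))
  P <- matrix(FALSE, length(genes), length(procs),
              dimnames = list(genes, procs))
  P[cbind(go$annotations$gene_id, go$annotations$process_id)] <- TRUE

  stat_of <- function(set) {
    hit_genes <- colSums(M[set, , drop = FALSE]) > 0
    cnt <- colSums(P[hit_genes, , drop = FALSE])
    if (statistic == "presence") as.integer(cnt > 0) else as.integer(cnt)
  }
  obs <- stat_of(obs_set)
  k <- length(obs_set)
  exceed <- integer(length(obs))
  with_seed(seed, {
    for (b in seq_len(B)) {
      idx <- rownames(M)[sample(nrow(M), k, replace = replace)]
      exceed <- exceed + (stat_of(idx) >= obs)
    }
  })
  p <- empirical_p(exceed, B)
  structure(data.frame(unit = procs, observed = obs, B = B,
                       null_exceed = exceed, p_emp = p, enriched = p < alpha,
                       row.names = NULL, stringsAsFactors = FALSE),
            seed = seed)
}

#' Hypergeometric GO over-representation test
#'
#' For each biological process annotated in the background, the upper-tail
#' hypergeometric probability of observing at least the seen overlap between
#' the target genes and the process's genes, with Benjamini-Hochberg
#' adjustment across processes. This is a plain over-representation test, an
#' approximation of the external genomic-enrichment tool it replaces.
#'
#' @param target_genes character vector of genes of interest (must be a subset
#'   of the background universe)
#' @param go GO annotation list from [read_go()]
#' @param background optional background gene universe (default `go$background`)
#' @return data.frame per process: unit, overlap, n_annotated, n_targets,
#'   n_background, p, q (BH-adjusted)
#' @export
genomic_go_enrichment <- function(target_genes, go, background = go$background) {
  target_genes <- unique(target_genes)
  if (!length(target_genes)) stop("empty target gene set")
  if (!all(target_genes %in% background))
    stop("target gene(s) outside the background universe: ",
         paste(utils::head(setdiff(target_genes, background), 5), collapse = ", "))
  ann <- go$annotations[go$annotations$gene_id %in% background, , drop = FALSE]
  by_proc <- split(ann$gene_id, ann$process_id)
  by_proc <- by_proc[lengths(by_proc) > 0]
  N <- length(unique(background)); n <- length(target_genes)
  res <- do.call(rbind, lapply(names(by_proc), function(pid) {
    K <- length(unique(by_proc[[pid]]))
    k <- length(intersect(target_genes, by_proc[[pid]]))
    data.frame(unit = pid, overlap = k, n_annotated = K, n_targets = n,
               n_background = N,
               p = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}

#' Disease-association bootstrap for a PD-miRNA set
#'
#' The observed count is the number of miRNAs in `pd_set` with at least one
#' disease association. Each of B replicates samples `length(pd_set)` miRNAs
#' from the catalog (with replacement by default — a bootstrap) and recomputes
#' the count; returns the null mean, the 2.5/97.5 percentile interval and the
#' add-one empirical p.
#'
#' @param pd_set character vector of miRNA ids (the paper's usage: the 31
#'   PD-miRNAs)
#' @param disease_db DiseaseAssociationTable from [read_disease()]
#' @param catalog_ids candidate pool of miRNA ids
#' @param B replicate count (default 10000)
#' @param seed RNG seed
#' @param replace sample with replacement (default TRUE)
#' @return list: observed_count, expectation, ci95 (lo, hi), p_emp, B, seed
#' @export
disease_bootstrap <- function(pd_set, disease_db, catalog_ids, B = 10000,
                              seed = 1, replace = TRUE) {
  if (B < 1) stop("B must be >= 1")
  k <- length(pd_set)
  if (!replace && k > length(catalog_ids))
    stop("pd_set larger than catalog in without-replacement mode")
  associated <- unique(disease_db$mirna_id)
  observed <- sum(pd_set %in% associated)
  has_assoc <- catalog_ids %in% associated
  null <- with_seed(seed, {
    vapply(seq_len(B),
           function(b) sum(has_assoc[sample(length(catalog_ids), k,
                                            replace = replace)]),
           integer(1))
  })
  list(observed_count = observed,
       expectation = mean(null),
       ci95 = unname(quantile(null, c(0.025, 0.975), type = 7)),
       p_emp = empirical_p(sum(null >= observed), B),
       B = B, seed = seed)
}
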