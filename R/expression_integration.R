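# Expression grouping, stratified TSS profiles, paired t-tests and
# cross-method concordance.

#' Group genes by expression level
#'
#' Genes with fewer than 10 reads are "repressed". The remaining genes are
#' ranked by count (ties broken by `gene_id` order, deterministic) and split
#' at the median: lower half "low", upper half "high"; an odd remainder puts
#' the extra gene in "low". With the usual 60% repressed fraction this yields
#' the 60/20/20 repressed/low/high partition.
#'
#' @param counts data.table with `gene_id` and `count` (non-negative).
#' @return data.table (`gene_id`, `count`, `class`). A message flags the case
#'   where every gene is repressed.
#' @export
group_by_expression <- function(counts) {
  dt <- as.data.table(counts)[, .(gene_id, count)]
  if (nrow(dt) == 0L) stop("empty expression table", call. = FALSE)
  if (any(dt$count < 0)) stop("counts must be non-negative", call. = FALSE)
  dt[, class := NA_character_]
  dt[count < 10L, class := "repressed"]
  rest <- dt[count >= 10L]
  if (nrow(rest) == 0L) {
    message("all genes repressed: low/high classes empty")
  } else {
    rest <- rest[order(count, gene_id)]
    n_low <- ceiling(nrow(rest) / 2)
    low_ids <- rest$gene_id[seq_len(n_low)]
    dt[gene_id %in% low_ids, class := "low"]
    dt[is.na(class), class := "high"]
  }
  setorder(dt, gene_id)
  dt[]
}

#' Expression- and CpG-class-stratified TSS meta-profiles
#'
#' Applies [tss_meta_profile()] to each (expression class x CpG class)
#' gene subset, per animal.
#'
#' @param calls_list Named list of coverage-filtered call tables, one per
#'   animal.
#' @param genes Gene table.
#' @param groups Output of [group_by_expression()].
#' @param cpg_classes Output of [tss_cpg_content()]; if NULL a single "all"
#'   CpG class is used.
#' @param genome,flank,window,step Passed to [tss_meta_profile()].
#' @return data.table (`animal`, `expr_class`, `cpg_class`, `offset`,
#'   `mean_meth`, `n_genes`). Empty strata are flagged with a message and
#'   omitted.
#' @export
stratified_tss_profiles <- function(calls_list, genes, groups,
                                    cpg_classes = NULL, genome = NULL,
                                    flank = 6000L, window = 1000L, step = 50L) {
  g <- as.data.table(genes)
  g[, expr_class := groups$class[match(g$gene_id, groups$gene_id)]]
  g[, cpg_class := if (is.null(cpg_classes)) "all" else
    cpg_classes$class[match(g$gene_id, cpg_classes$gene_id)]]
  if (is.null(names(calls_list)))
    names(calls_list) <- sprintf("animal_%d", seq_along(calls_list))
  strata <- unique(g[!is.na(expr_class) & !is.na(cpg_class),
                     .(expr_class, cpg_class)])
  out <- rbindlist(lapply(names(calls_list), function(an) {
    rbindlist(lapply(seq_len(nrow(strata)), function(si) {
      sub <- g[expr_class == strata$expr_class[si] &
                 cpg_class == strata$cpg_class[si]]
      if (nrow(sub) == 0L) {
        message("empty stratum: ", strata$expr_class[si], " / ",
                strata$cpg_class[si])
        return(NULL)
      }
      p <- tss_meta_profile(calls_list[[an]], sub, genome = genome,
                            flank = flank, window = window, step = step)
      p[, `:=`(animal = an, expr_class = strata$expr_class[si],
               cpg_class = strata$cpg_class[si])]
      p
    }))
  }))
  setcolorder(out, c("animal", "expr_class", "cpg_class"))
  out[]
}

#' Paired t-test on per-pair differences
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with the n-1 sd denominator, df = n-1,
#' two-sided p from the t distribution. A zero-variance difference vector is
#' degenerate: p = 1 when the mean is 0, else p = 0, flagged.
#'
#' @param d Numeric vector of per-pair differences (n >= 2).
#' @return List of class `paired_t`: `n`, `mean_diff`, `sed` (standard error
#'   of the difference), `t`, `df`, `p`, `degenerate`.
#' @export
paired_t_test <- function(d) {
  d <- as.numeric(d)
  n <- length(d)
  if (n < 2L) stop("insufficient_pairs", call. = FALSE)
  m <- mean(d)
  s <- sd(d)
  if (s == 0) {
    return(structure(list(n = n, mean_diff = m, sed = 0, t = NA_real_,
                          df = n - 1L, p = if (m == 0) 1 else 0,
                          degenerate = TRUE), class = "paired_t"))
  }
  sed <- s / sqrt(n)
  tval <- m / sed
  structure(list(n = n, mean_diff = m, sed = sed, t = tval, df = n - 1L,
                 p = 2 * pt(-abs(tval), df = n - 1L), degenerate = FALSE),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("paired t-test: n=%d, mean diff=%.3f, sed=%.3f, t=%.3f, df=%d, p=%.4g%s\n",
              x$n, x$mean_diff, x$sed, x$t, x$df, x$p,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Cross-method per-site concordance
#'
#' For each CpG site measured by two methods in the same animals, a paired
#' t-test across animals (pairs = animals) decides whether the methods are
#' indistinguishable (p >= alpha; no multiple-testing correction by default).
#'
#' @param method_a,method_b data.tables (`site`, `animal`, `percent`).
#' @param alpha Significance level (default 0.05).
#' @param p_adjust_method Optional [stats::p.adjust()] method applied across
#'   sites before the alpha comparison (default "none").
#' @return List: `per_site` (data.table `site`, `n_animals`, `mean_diff`,
#'   `p`, `indistinguishable`), `n_sites`, `n_indistinguishable`.
#' @export
method_concordance <- function(method_a, method_b, alpha = 0.05,
                               p_adjust_method = "none") {
  a <- as.data.table(method_a)
  b <- as.data.table(method_b)
  shared <- merge(a[, .(site, animal, pa = percent)],
                  b[, .(site, animal, pb = percent)],
                  by = c("site", "animal"))
  dropped <- setdiff(union(a$site, b$site), shared$site)
  if (length(dropped))
    message(length(dropped), " site(s) present in only one table excluded")
  n_animals <- shared[, .N, by = site]
  if (nrow(shared) == 0L || max(n_animals$N) < 2L)
    stop("need the same sites measured in >= 2 animals", call. = FALSE)
  shared <- shared[site %in% n_animals[N >= 2L, site]]
  per_site <- shared[, {
    tt <- paired_t_test(pa - pb)
    .(n_animals = tt$n, mean_diff = tt$mean_diff, p = tt$p)
  }, by = site]
  per_site[, p_adj := stats::p.adjust(p, method = p_adjust_method)]
  per_site[, indistinguishable := p_adj >= alpha]
  list(per_site = per_site[], n_sites = nrow(per_site),
       n_indistinguishable = sum(per_site$indistinguishable))
}
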