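# GO term enrichment with DAG decorrelation.
#
# Annotations are first closed over is_a ancestors ("a gene annotated to a
# term is annotated to all its parents"). Scoring is Fisher's exact upper
# tail (hypergeometric survival). The default method is `elim`: terms are
# processed leaves-first, and whenever a term scores below `elim_cut` its
# genes are removed from all ancestors before those are tested, which
# decorrelates related terms. P values are deliberately NOT corrected for
# multiple testing: the per-term tests are not independent.

#' Propagate annotations to ancestor terms
#'
#' @param annotations data.frame with columns `gene`, `term`.
#' @param dag an `ontology_dag` from [parse_obo()].
#' @return annotation data.frame closed over ancestors (unique gene/term
#'   pairs); idempotent.
#' @export
propagate <- function(annotations, dag) {
  unknown <- !annotations$term %in% dag$terms
  if (any(unknown)) {
    i <- which(unknown)[1]
    stop(sprintf("gene %s annotated to unknown term %s",
                 annotations$gene[i], annotations$term[i]), call. = FALSE)
  }
  anc <- lapply(setNames(dag$terms, dag$terms),
                function(t) c(t, ancestors(dag, t)))
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    data.frame(gene = annotations$gene[i],
               term = anc[[annotations$term[i]]], stringsAsFactors = FALSE)
  })
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Fisher's exact upper-tail p value
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated genes in a study set of size `n` drawn from `N`
#' genes of which `K` carry the annotation.
#'
#' @param k annotated genes in the study set.
#' @param n study-set size.
#' @param K annotated genes in the background.
#' @param N background size.
#' @return the p value.
#' @export
fisher_p <- function(k, n, K, N) {
  if (any(k < 0, n < 0, K < 0, N < 0) || k > n || n > N || K > N || k > K)
    stop("inconsistent hypergeometric counts", call. = FALSE)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' GO term enrichment of a study gene set
#'
#' @param study character vector of study genes (must be a subset of
#'   `background`; must be non-empty).
#' @param background character vector of background genes.
#' @param annotations ancestor-closed annotation data.frame (`gene`,
#'   `term`); see [propagate()].
#' @param dag an `ontology_dag`.
#' @param method `"elim"` (default) or `"classic"`; the result always
#'   carries both p values, `method` selects which one drives
#'   `significant`.
#' @param alpha significance threshold (default 0.01, uncorrected).
#' @param elim_cut p threshold below which a term's genes are eliminated
#'   from its ancestors (default = `alpha`).
#' @param min_term_size terms with fewer background genes are reported with
#'   p = 1 (default 1).
#' @return data.frame: `term`, `name`, `k`, `n`, `K`, `N`, `p_classic`,
#'   `p_elim`, `significant`; every DAG term is reported (zero-annotation
#'   terms with p = 1).
#' @export
enrich <- function(study, background, annotations, dag,
                   method = c("elim", "classic"), alpha = 0.01,
                   elim_cut = alpha, min_term_size = 1) {
  method <- match.arg(method)
  if (length(study) == 0) stop("empty study set", call. = FALSE)
  if (!all(study %in% background))
    stop("study set is not a subset of the background", call. = FALSE)
  ann <- annotations[annotations$gene %in% background, , drop = FALSE]
  term_genes <- split(ann$gene, factor(ann$term, levels = dag$terms))
  term_genes <- lapply(term_genes, unique)
  N <- length(unique(background))
  n <- length(unique(study))

  p_classic <- setNames(rep(1, length(dag$terms)), dag$terms)
  k_vec <- setNames(rep(0L, length(dag$terms)), dag$terms)
  K_vec <- setNames(rep(0L, length(dag$terms)), dag$terms)
  for (t in dag$terms) {
    g <- term_genes[[t]]
    K <- length(g); k <- length(intersect(g, study))
    k_vec[t] <- k; K_vec[t] <- K
    if (K >= min_term_size && K > 0)
      p_classic[t] <- fisher_p(k, n, K, N)
  }

  # elim: leaves first (deepest terms processed before their ancestors)
  depth <- term_depths(dag)
  order_terms <- dag$terms[order(-depth[dag$terms])]
  removed <- setNames(vector("list", length(dag$terms)), dag$terms)
  p_elim <- setNames(rep(1, length(dag$terms)), dag$terms)
  anc_cache <- lapply(setNames(dag$terms, dag$terms),
                      function(t) ancestors(dag, t))
  for (t in order_terms) {
    g <- setdiff(term_genes[[t]], removed[[t]])
    K <- length(g); k <- length(intersect(g, study))
    if (K >= min_term_size && K > 0)
      p_elim[t] <- fisher_p(k, n, K, N)
    if (p_elim[t] < elim_cut) {
      for (a in anc_cache[[t]])
        removed[[a]] <- union(removed[[a]], g)
    }
  }

  p_sel <- if (method == "elim") p_elim else p_classic
  data.frame(term = dag$terms,
             name = unname(dag$names[dag$terms]),
             k = unname(k_vec), n = n, K = unname(K_vec), N = N,
             p_classic = unname(p_classic), p_elim = unname(p_elim),
             significant = unname(p_sel) < alpha,
             stringsAsFactors = FALSE)
}
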