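# Likelihood-ratio validation of candidate co-occurrence edges.
#
# For entities a and g, presence/absence over the N paragraphs gives a 2x2
# table; the Dunning log-likelihood ratio compares binomial likelihoods of
# "P(a | g present) = P(a | g absent)" against unequal rates. Under
# independence the statistic is asymptotically chi-square with 1 df, which
# supplies the significance cut-off. Direction classes operationalize
# "p(a) ~= p(a,g)": when most paragraphs containing a also contain g, the
# relation is read as a -> g; when both conditionals are high, bidirectional.

#' Construct a 2x2 contingency table
#'
#' @param k11 Paragraphs containing both entities.
#' @param k12 Paragraphs containing only `a`.
#' @param k21 Paragraphs containing only `g`.
#' @param k22 Paragraphs containing neither.
#' @return Object of class `contingency_table` (named integer vector).
#' @export
contingency_table <- function(k11, k12, k21, k22) {
  k <- c(k11 = k11, k12 = k12, k21 = k21, k22 = k22)
  if (any(is.na(k)) || any(k < 0)) {
    stop("contingency cells must be non-negative", call. = FALSE)
  }
  if (sum(k) < 1) stop("contingency table is empty (N = 0)", call. = FALSE)
  structure(as.integer(k), names = names(k), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- matrix(unclass(x), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "no a"), c("g", "no g")))
  print(m)
  invisible(x)
}

# x*log(q) with the 0*log(0) = 0 convention, vectorized.
xlog <- function(x, q) ifelse(x > 0, x * log(q), 0)

llr_core <- function(k11, k12, k21, k22) {
  n1 <- k11 + k21
  n2 <- k12 + k22
  x1 <- k11
  x2 <- k12
  if (any(x1 + x2 < 1) || any(n1 < 1)) {
    stop("log-likelihood ratio undefined: zero marginal", call. = FALSE)
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  ll <- function(x, n, q) xlog(x, q) + xlog(n - x, 1 - q)
  llr <- 2 * (ll(x1, n1, p1) + ll(x2, n2, p2) - ll(x1, n1, p) - ll(x2, n2, p))
  pmax(llr, 0)
}

#' Dunning log-likelihood-ratio collocation score
#'
#' With n1 = k11+k21 paragraphs containing g and n2 = k12+k22 without, the
#' statistic is 2\[l(x1,n1,p1) + l(x2,n2,p2) - l(x1,n1,p) - l(x2,n2,p)\]
#' where l(x,n,q) = x log q + (n-x) log(1-q), x1 = k11, x2 = k12,
#' p1 = x1/n1, p2 = x2/n2 and p is the pooled rate. Zero at exact
#' independence; clamped at 0 against rounding. Symmetric in the roles of
#' the two entities.
#'
#' @param t A [contingency_table()], or `k11` given as four separate cells.
#' @param k12,k21,k22 Remaining cells when `t` is the `k11` count.
#' @return Non-negative score, asymptotically chi-square (1 df) under
#'   independence.
#' @export
llr_score <- function(t, k12 = NULL, k21 = NULL, k22 = NULL) {
  if (inherits(t, "contingency_table")) {
    return(llr_core(t[["k11"]], t[["k12"]], t[["k21"]], t[["k22"]]))
  }
  if (is.null(k12)) {
    if (length(t) != 4L) {
      stop("supply a contingency_table or four cells", call. = FALSE)
    }
    return(llr_core(t[1], t[2], t[3], t[4]))
  }
  llr_core(t, k12, k21, k22)
}

#' Significance of an LLR score
#'
#' @param llr Score(s) from [llr_score()].
#' @param alpha Significance level in (0, 1).
#' @return `TRUE` iff `llr` reaches the chi-square (1 df) critical value at
#'   `alpha` (e.g. 3.8415 at alpha = 0.05).
#' @export
is_significant <- function(llr, alpha = 0.05) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  }
  llr >= stats::qchisq(1 - alpha, df = 1)
}

#' Direction class of a co-occurrence relation
#'
#' r_a = k11/(k11+k12) is the fraction of a's paragraphs that also contain
#' g (operationalizing p(a) ~= p(a,g)); r_g symmetrically. Both at or above
#' `tau`: bidirectional; only r_a: `a_to_g`; only r_g: `g_to_a`; neither:
#' undirected.
#'
#' @param t A [contingency_table()] with both marginals positive.
#' @param tau Conditional-probability threshold in (0, 1], default 0.8.
#' @return One of `"bidirectional"`, `"a_to_g"`, `"g_to_a"`, `"undirected"`.
#' @export
direction <- function(t, tau = 0.8) {
  stopifnot(inherits(t, "contingency_table"))
  if (length(tau) != 1L || is.na(tau) || tau <= 0 || tau > 1) {
    stop("tau must lie in (0, 1]", call. = FALSE)
  }
  ca <- t[["k11"]] + t[["k12"]]
  cg <- t[["k11"]] + t[["k21"]]
  if (ca < 1 || cg < 1) stop("direction undefined: zero marginal",
                             call. = FALSE)
  direction_class(t[["k11"]] / ca, t[["k11"]] / cg, tau)
}

direction_class <- function(r_a, r_g, tau) {
  ifelse(r_a >= tau & r_g >= tau, "bidirectional",
         ifelse(r_a >= tau, "a_to_g",
                ifelse(r_g >= tau, "g_to_a", "undirected")))
}

#' Score every admissible candidate pair
#'
#' Every admissible pair with at least `min_pair_count` co-occurring
#' paragraphs is scored with the LLR test and classified by direction.
#' Within each pair the chemical is entity `a` (the shared type of both
#' relation kinds), so `a_to_g` always reads "chemical to partner".
#'
#' @param counts A `cooc_counts` object (see [count_cooccurrences()]).
#' @param alpha Significance level, default 0.05.
#' @param tau Direction threshold, default 0.8.
#' @param min_pair_count Minimum paragraph co-occurrence count for a pair to
#'   be scored, default 1 (permissive: every observed co-occurrence).
#' @param correction `"none"` (default; no multiple-testing correction) or
#'   `"bonferroni"` over the scored pairs.
#' @return `data.frame` with one row per scored pair: `entity_a`, `type_a`,
#'   `entity_g`, `type_g`, `relation`, the four cells, `llr`, `significant`,
#'   `direction`, `pair_occ` and `weight`; `alpha` and `tau` are attached as
#'   attributes.
#' @export
decide_edges <- function(counts, alpha = 0.05, tau = 0.8,
                         min_pair_count = 1L,
                         correction = c("none", "bonferroni")) {
  stopifnot(inherits(counts, "cooc_counts"))
  correction <- match.arg(correction)
  p <- counts$pairs[counts$pairs$pair_occ >= min_pair_count, , drop = FALSE]
  empty <- data.frame(entity_a = character(), type_a = character(),
                      entity_g = character(), type_g = character(),
                      relation = character(), k11 = integer(),
                      k12 = integer(), k21 = integer(), k22 = integer(),
                      llr = numeric(), significant = logical(),
                      direction = character(), pair_occ = integer(),
                      weight = integer(), stringsAsFactors = FALSE)
  if (nrow(p) == 0L) {
    attr(empty, "alpha") <- alpha; attr(empty, "tau") <- tau
    return(empty)
  }
  # orient so that the chemical is entity a
  a_first <- p$etype_1 == "chemical"
  ent_a <- ifelse(a_first, p$canonical_1, p$canonical_2)
  typ_a <- ifelse(a_first, p$etype_1, p$etype_2)
  ent_g <- ifelse(a_first, p$canonical_2, p$canonical_1)
  typ_g <- ifelse(a_first, p$etype_2, p$etype_1)
  ekey <- entity_key(counts$entities$canonical, counts$entities$etype)
  ca <- counts$entities$count[match(entity_key(ent_a, typ_a), ekey)]
  cg <- counts$entities$count[match(entity_key(ent_g, typ_g), ekey)]
  k11 <- p$pair_occ
  k12 <- ca - k11
  k21 <- cg - k11
  k22 <- counts$N - ca - cg + k11
  llr <- llr_core(k11, k12, k21, k22)
  eff_alpha <- if (correction == "bonferroni") alpha / nrow(p) else alpha
  res <- data.frame(entity_a = ent_a, type_a = typ_a, entity_g = ent_g,
                    type_g = typ_g,
                    relation = ifelse(typ_g == "gene", "gene_chemical",
                                      "chemical_property"),
                    k11 = k11, k12 = k12, k21 = k21, k22 = k22, llr = llr,
                    significant = is_significant(llr, eff_alpha),
                    direction = direction_class(k11 / ca, k11 / cg, tau),
                    pair_occ = p$pair_occ, weight = p$pair_weight,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "alpha") <- alpha
  attr(res, "tau") <- tau
  attr(res, "correction") <- correction
  res
}

#' Write the association report
#'
#' @param assoc Result of [decide_edges()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_association_report <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
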