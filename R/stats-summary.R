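#' Kruskal-Wallis rank test across groups
#'
#' Mid-rank ties and tie correction, chi-square reference distribution with
#' `g - 1` degrees of freedom (the standard large-sample form, as in
#' `stats::kruskal.test`). All-identical values give `H = 0`, `p = 1`.
#'
#' For very small samples (total `N <= exact_max`) the chi-square reference
#' is a poor approximation of the permutation distribution, so an exact
#' p-value is reported alongside: the tail probability of `H` over all
#' assignments of the pooled values to groups of the observed sizes.
#'
#' @param groups list of two or more numeric vectors (`NA`s dropped).
#' @param exact_max largest total sample size for which the exact
#'   permutation p-value is also computed (default 10).
#' @return list `H`, `df`, `p` (chi-square), `p_exact` (`NA` above
#'   `exact_max`).
#' @export
kruskal_wallis <- function(groups, exact_max = 10) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  stopifnot(length(groups) >= 2L, all(lengths(groups) >= 1L),
            sum(lengths(groups)) >= 3L)
  if (length(unique(unlist(groups))) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1, p_exact = 1))
  }
  kt <- kruskal.test(groups)
  H <- unname(kt$statistic)
  N <- sum(lengths(groups))
  p_exact <- NA_real_
  if (N <= exact_max) {
    pooled <- unlist(groups)
    sizes <- lengths(groups)
    Hs <- kw_enumerate(pooled, sizes)
    p_exact <- mean(Hs >= H - 1e-12)
  }
  list(H = H, df = unname(kt$parameter), p = unname(kt$p.value),
       p_exact = p_exact)
}

# H statistic for every assignment of the pooled values to groups of the
# given sizes (exhaustive; intended for total N <= 10)
kw_enumerate <- function(pooled, sizes) {
  N <- length(pooled)
  r <- rank(pooled)          # mid-ranks, fixed across assignments
  tie_corr <- 1 - sum(vapply(split(r, r), function(g)
    length(g)^3 - length(g), 1.0)) / (N^3 - N)
  H_of <- function(group_ranks) {
    s <- vapply(group_ranks, sum, 1.0)
    h <- 12 / (N * (N + 1)) * sum(s^2 / lengths(group_ranks)) - 3 * (N + 1)
    h / tie_corr
  }
  out <- c()
  recurse <- function(avail, gi, acc) {
    if (gi == length(sizes)) {
      out[[length(out) + 1L]] <<- H_of(c(acc, list(r[avail])))
      return(invisible())
    }
    cmb <- combn(avail, sizes[gi])
    for (j in seq_len(ncol(cmb))) {
      idx <- cmb[, j]
      recurse(setdiff(avail, idx), gi + 1L, c(acc, list(r[idx])))
    }
  }
  recurse(seq_len(N), 1L, list())
  unlist(out)
}

#' Bonferroni family-wise adjustment
#'
#' `p_adj = min(1, p * family_size)`; the family is the set of features
#' tested within one contrast table.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param family_size number of tests in the declared family (default
#'   `length(pvals)`).
#' @return adjusted p-values, elementwise in `[p, 1]`.
#' @export
bonferroni <- function(pvals, family_size = length(pvals)) {
  pmin(1, pvals * family_size)
}

#' Chi-square test of a POS/NEG segment-count split
#'
#' Goodness-of-fit of `(pos, neg)` against an equal split, 1 df, no
#' continuity correction. For totals below 10 an exact two-sided binomial
#' p-value is reported alongside. A zero total yields `NA` (unobserved
#' cell).
#'
#' @param pos,neg non-negative counts.
#' @return list `chisq`, `p`, `p_exact` (`NA` unless `pos + neg < 10`).
#' @export
chi_square_emotion <- function(pos, neg) {
  if (pos + neg == 0) return(list(chisq = NA_real_, p = NA_real_,
                                  p_exact = NA_real_))
  ct <- suppressWarnings(chisq.test(c(pos, neg), p = c(0.5, 0.5)))
  p_exact <- if (pos + neg < 10) {
    unname(binom.test(pos, pos + neg, 0.5)$p.value)
  } else NA_real_
  list(chisq = unname(ct$statistic), p = unname(ct$p.value),
       p_exact = p_exact)
}

#' Pearson correlation with a t-test on the coefficient
#'
#' `t = r sqrt(n - 2) / sqrt(1 - r^2)`, two-sided p from the t distribution
#' with `n - 2` df (as `stats::cor.test`).
#'
#' @param x,y numeric vectors, `n >= 3` complete pairs.
#' @return list `r`, `t`, `df`, `p`; all `NA` when either input has zero
#'   variance.
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  stopifnot(length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, t = NA_real_, df = length(x) - 2L, p = NA_real_))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = unname(ct$p.value))
}

#' Feature contrast table by coupling directionality
#'
#' The per-segment coupling classes are joined with per-segment,
#' per-participant feature values; both participant orderings are
#' enumerated, so each segment contributes one directed observation per
#' participant (the second participant's lag class is the negation of the
#' first's, the correlation class is shared). Per feature, values are split
#' by class, summarized as median and IQR, tested with [kruskal_wallis()]
#' and Bonferroni-adjusted over the table's feature family. `ZERO`-lag
#' segments are excluded from lag contrasts.
#'
#' @param features data.frame `(segment_id, participant_id, feature, value)`
#'   in long form.
#' @param coupling data.frame from [couple_session()].
#' @param by `"lag"` or `"correlation"`.
#' @param participants participant ids in track order (reference first);
#'   default derived from `features`.
#' @return data.frame, one row per feature: medians and quartiles per class,
#'   group sizes, raw and adjusted p (rows with a group smaller than 3 are
#'   flagged `low_n`).
#' @export
build_contrast_table <- function(features, coupling, by = c("lag", "correlation"),
                                 participants = NULL) {
  by <- match.arg(by)
  if (is.null(participants)) participants <- unique(features$participant_id)
  stopifnot(length(participants) == 2L)
  cls_col <- if (by == "lag") "lag_class" else "corr_class"
  seg_cls <- coupling[!is.na(coupling[[cls_col]]), c("segment_id", cls_col)]
  directed <- rbind(
    data.frame(segment_id = seg_cls$segment_id,
               participant_id = participants[1], class = seg_cls[[cls_col]]),
    data.frame(segment_id = seg_cls$segment_id,
               participant_id = participants[2],
               class = if (by == "lag") flip_lag_class(seg_cls[[cls_col]])
               else seg_cls[[cls_col]]))
  directed <- directed[directed$class %in% c("POS", "NEG"), , drop = FALSE]
  d <- merge(features, directed, by = c("segment_id", "participant_id"))
  feats <- unique(d$feature)
  rows <- lapply(feats, function(f) {
    df <- d[d$feature == f & !is.na(d$value), , drop = FALSE]
    pos <- df$value[df$class == "POS"]
    neg <- df$value[df$class == "NEG"]
    qs <- function(v) if (length(v)) quantile(v, c(0.25, 0.5, 0.75), type = 7,
                                              names = FALSE) else rep(NA_real_, 3)
    qp <- qs(pos); qn <- qs(neg)
    p_raw <- if (length(pos) >= 1L && length(neg) >= 1L &&
                 length(pos) + length(neg) >= 3L) {
      kruskal_wallis(list(pos, neg))$p
    } else NA_real_
    data.frame(feature = f,
               pos_median = qp[2], pos_q25 = qp[1], pos_q75 = qp[3],
               neg_median = qn[2], neg_q25 = qn[1], neg_q75 = qn[3],
               n_pos = length(pos), n_neg = length(neg),
               p_raw = p_raw,
               low_n = length(pos) < 3L || length(neg) < 3L)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bonferroni(out$p_raw, family_size = nrow(out))
  out$trend <- !is.na(out$p_adj) & out$p_adj >= 0.05 & out$p_adj < 0.1
  rownames(out) <- NULL
  out
}

#' Emotion-state distribution table by coupling directionality
#'
#' Counts POS/NEG segments per emotion dimension, perspective and state;
#' percentages are column-wise per state (`pos / (pos + neg)`); each cell
#' pair is tested with [chi_square_emotion()]. A pooled `total` row per
#' dimension aggregates over perspectives.
#'
#' @param segments data.frame from [attach_emotions()] (dominant-emotion
#'   columns present).
#' @param coupling data.frame from [couple_session()].
#' @param by `"lag"` or `"correlation"`.
#' @return data.frame `(dimension, perspective, state, pos_count, neg_count,
#'   pos_pct, neg_pct, chisq, p, p_exact)`.
#' @export
build_emotion_table <- function(segments, coupling, by = c("lag", "correlation")) {
  by <- match.arg(by)
  cls_col <- if (by == "lag") "lag_class" else "corr_class"
  cp <- coupling[!is.na(coupling[[cls_col]]) &
                   coupling[[cls_col]] %in% c("POS", "NEG"),
                 c("segment_id", cls_col)]
  d <- merge(segments, cp, by = "segment_id")
  emo_cols <- grep("_(arousal|valence)$", names(d), value = TRUE)
  rows <- list()
  for (dim in c("arousal", "valence")) {
    cols <- grep(paste0("_", dim, "$"), emo_cols, value = TRUE)
    pooled_pos <- integer(5); pooled_neg <- integer(5)
    for (col in cols) {
      persp <- sub(paste0("_", dim, "$"), "", col)
      for (s in 1:5) {
        pos <- sum(d[[col]] == s & d[[cls_col]] == "POS", na.rm = TRUE)
        neg <- sum(d[[col]] == s & d[[cls_col]] == "NEG", na.rm = TRUE)
        pooled_pos[s] <- pooled_pos[s] + pos
        pooled_neg[s] <- pooled_neg[s] + neg
        ct <- chi_square_emotion(pos, neg)
        tot <- pos + neg
        rows[[length(rows) + 1L]] <- data.frame(
          dimension = dim, perspective = persp, state = s,
          pos_count = pos, neg_count = neg,
          pos_pct = if (tot > 0) 100 * pos / tot else NA_real_,
          neg_pct = if (tot > 0) 100 * neg / tot else NA_real_,
          chisq = ct$chisq, p = ct$p, p_exact = ct$p_exact)
      }
    }
    for (s in 1:5) {
      ct <- chi_square_emotion(pooled_pos[s], pooled_neg[s])
      tot <- pooled_pos[s] + pooled_neg[s]
      rows[[length(rows) + 1L]] <- data.frame(
        dimension = dim, perspective = "total", state = s,
        pos_count = pooled_pos[s], neg_count = pooled_neg[s],
        pos_pct = if (tot > 0) 100 * pooled_pos[s] / tot else NA_real_,
        neg_pct = if (tot > 0) 100 * pooled_neg[s] / tot else NA_real_,
        chisq = ct$chisq, p = ct$p, p_exact = ct$p_exact)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Omnibus association between coupling directionality and emotion states
#'
#' Pearson chi-square test of the 2 x states contingency table (POS/NEG
#' segment counts across emotion states) for one dimension and perspective
#' of an emotion distribution table — the overall association the
#' per-state cell tests decompose.
#'
#' @param emotion_table data.frame from [build_emotion_table()].
#' @param dimension `"arousal"` or `"valence"`.
#' @param perspective one of `"self"`, `"partner"`, `"external"`, `"total"`.
#' @return list `chisq`, `df`, `p` (`p = NA` when fewer than two states have
#'   any segments).
#' @export
emotion_association_test <- function(emotion_table, dimension = "arousal",
                                     perspective = "self") {
  d <- emotion_table[emotion_table$dimension == dimension &
                       emotion_table$perspective == perspective, , drop = FALSE]
  m <- rbind(d$pos_count, d$neg_count)
  keep <- colSums(m) > 0
  if (sum(keep) < 2L || sum(m) == 0) {
    return(list(chisq = NA_real_, df = NA_integer_, p = NA_real_))
  }
  ct <- suppressWarnings(chisq.test(m[, keep, drop = FALSE]))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}
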