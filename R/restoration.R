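#' Seven-way restoration categories
#' @export
restoration_categories <- c("restored", "partially_restored", "over_restored",
                            "reinforced", "unrestored", "novel",
                            "uninformative")

#' Collapse a seven-way category to the figure-level grouping
#'
#' `restored`, `partially_restored` and `over_restored` collapse to
#' `restorative`; the remaining categories map to themselves.
#'
#' @param category character vector of seven-way categories.
#' @return character vector of collapsed categories.
#' @export
collapse_restoration <- function(category) {
  ifelse(category %in% c("restored", "partially_restored", "over_restored"),
         "restorative", category)
}

#' Assign one restoration category from the test pattern and geometry
#'
#' The decision rule, applied per retained principal component, uses three
#' significance indicators -- `sig_a`: the ancestor moved between 37 C and the
#' stress temperature (ancestral plasticity); `sig_s`: the evolved strain
#' differs from the ancestor at the stress temperature; `sig_o`: the evolved
#' strain differs from the ancestor at 37 C -- plus the positions of the
#' evolved mean `e` relative to the ancestor centroids `a_s` (stress) and
#' `a_o` (optimum):
#' \itemize{
#'  \item no plasticity, no movement: `uninformative`;
#'  \item no plasticity, but the evolved strain moved: `novel`;
#'  \item plasticity, evolved still at the ancestral stressed state:
#'    `unrestored`;
#'  \item evolved left the stressed state and is indistinguishable from the
#'    37 C state: `restored`;
#'  \item all three significant with `e` strictly between the centroids:
#'    `partially_restored`;
#'  \item all three significant with `e` past the 37 C centroid (away from
#'    the stressed state): `over_restored`;
#'  \item all three significant with `e` past the stressed centroid (away
#'    from 37 C): `reinforced`.
#' }
#' The seven categories are mutually exclusive and exhaustive over every
#' significance pattern and geometric position.
#'
#' @param sig_a,sig_s,sig_o logical significance of the plasticity, stress
#'   and optimum contrasts.
#' @param a_o,a_s,e ancestor-at-37, ancestor-at-stress and evolved positions
#'   on the component.
#' @return one category string.
#' @export
restoration_category <- function(sig_a, sig_s, sig_o, a_o, a_s, e) {
  if (!sig_a && !sig_s) return("uninformative")
  if (!sig_a && sig_s) return("novel")
  if (sig_a && !sig_s) return("unrestored")
  if (!sig_o) return("restored")
  # all three significant: position decides
  if (e == a_s || e == a_o)
    stop_config("evolved mean coincides with a centroid although all tests are significant; inconsistent inputs")
  if (a_s == a_o)
    stop_config("ancestor centroids coincide although plasticity is significant; inconsistent inputs")
  lo <- min(a_s, a_o); hi <- max(a_s, a_o)
  if (e > lo && e < hi) return("partially_restored")
  beyond_o <- (a_o > a_s && e > a_o) || (a_o < a_s && e < a_o)
  if (beyond_o) "over_restored" else "reinforced"
}

#' Classify evolved strains' phenotypic responses per principal component
#'
#' For every evolved strain at every stress temperature (15 and 43 C), and
#' for every retained component, three two-sided t-tests are run on the
#' replicate scores: ancestor-at-stress vs ancestor-at-37 (plasticity,
#' `p_a`), evolved vs ancestor-at-stress (`p_s`), and evolved vs
#' ancestor-at-37 (`p_o`). Within each strain-temperature the component-wise
#' p-values of each test family are corrected for family-wise error (Holm by
#' default), and the significance pattern plus the component geometry yields
#' the [restoration_category()]. A per-strain headline call is the majority
#' collapsed category over informative components, ties broken toward the
#' less restorative state.
#'
#' @param model a [fit_pca()] model over all plates.
#' @param meta plate metadata aligned with the score rows; needs `plate_id`,
#'   `strain_id`, `lineage`, `temperature_C` and `role`
#'   (`"ancestor"`/`"evolved"`).
#' @param alpha significance level after correction.
#' @param fwer `"holm"` or `"bonferroni"`.
#' @param by ancestors matched per `"lineage"` or `"pooled"`.
#' @param optimum_temp the unstressed reference temperature.
#' @return object of class `restoration_calls`: data frame with one row per
#'   strain x stress temperature x component (`category`, `collapsed`,
#'   adjusted p-values, positions), with the per-strain summary from
#'   [summarize_restoration()] in attribute `"summary"`.
#' @export
classify_restoration <- function(model, meta, alpha = 0.05,
                                 fwer = c("holm", "bonferroni"),
                                 by = c("lineage", "pooled"),
                                 optimum_temp = 37) {
  fwer <- match.arg(fwer)
  by <- match.arg(by)
  stopifnot(inherits(model, "pca_model"), nrow(meta) == nrow(model$scores))
  k <- model$retained
  scores <- model$scores[, seq_len(k), drop = FALSE]
  cents <- ancestor_centroids(model, meta, by = by)
  reps <- attr(cents, "replicates")
  anc_scores <- function(group, temp) {
    key <- paste(group, temp, sep = "|")
    if (is.null(reps[[key]]))
      stop_config("missing ancestor condition: %s at %g C", group, temp)
    reps[[key]]
  }
  adj <- function(p) stats::p.adjust(p, method = fwer)

  ev_meta <- unique(meta[meta$role == "evolved" &
                           meta$temperature_C != optimum_temp,
                         c("strain_id", "lineage", "temperature_C")])
  out <- list()
  for (i in seq_len(nrow(ev_meta))) {
    sid <- ev_meta$strain_id[i]
    temp <- ev_meta$temperature_C[i]
    group <- if (by == "pooled") "pooled" else ev_meta$lineage[i]
    e_rows <- meta$role == "evolved" & meta$strain_id == sid &
      meta$temperature_C == temp
    if (sum(e_rows) < 2)
      stop_config("strain %s at %g C has fewer than 2 replicates", sid, temp)
    E <- scores[e_rows, , drop = FALSE]
    As <- anc_scores(group, temp)
    Ao <- anc_scores(group, optimum_temp)
    p_a <- p_s <- p_o <- numeric(k)
    for (c_ in seq_len(k)) {
      p_a[c_] <- stats::t.test(As[, c_], Ao[, c_], var.equal = TRUE)$p.value
      p_s[c_] <- stats::t.test(E[, c_], As[, c_], var.equal = TRUE)$p.value
      p_o[c_] <- stats::t.test(E[, c_], Ao[, c_], var.equal = TRUE)$p.value
    }
    p_a <- adj(p_a); p_s <- adj(p_s); p_o <- adj(p_o)
    cat_ <- character(k)
    for (c_ in seq_len(k)) {
      cat_[c_] <- restoration_category(p_a[c_] < alpha, p_s[c_] < alpha,
                                       p_o[c_] < alpha,
                                       a_o = mean(Ao[, c_]),
                                       a_s = mean(As[, c_]),
                                       e = mean(E[, c_]))
    }
    out[[i]] <- data.frame(
      strain_id = sid, temperature_C = temp, component = seq_len(k),
      category = cat_, collapsed = collapse_restoration(cat_),
      p_plasticity = p_a, p_stress = p_s, p_optimum = p_o,
      a_o = colMeans(Ao), a_s = colMeans(As), e = colMeans(E))
  }
  calls <- do.call(rbind, out)
  rownames(calls) <- NULL
  attr(calls, "summary") <- summarize_restoration(calls)
  class(calls) <- c("restoration_calls", class(calls))
  calls
}

# Conservative ordering: when a majority vote ties, prefer the call that
# claims less restoration.
restorative_rank <- c(unrestored = 1, reinforced = 2, novel = 3,
                      restorative = 4)

#' Headline restoration call per strain and stress temperature
#'
#' Majority vote of the collapsed categories over the informative components
#' (those not `uninformative`), ties broken toward the less restorative
#' category; a pair with no informative component is `uninformative`.
#'
#' @param calls per-component calls from [classify_restoration()].
#' @return data frame `strain_id`, `temperature_C`, `headline`,
#'   `n_informative`.
#' @export
summarize_restoration <- function(calls) {
  keys <- unique(calls[, c("strain_id", "temperature_C")])
  keys$headline <- NA_character_
  keys$n_informative <- 0L
  for (i in seq_len(nrow(keys))) {
    sub <- calls[calls$strain_id == keys$strain_id[i] &
                   calls$temperature_C == keys$temperature_C[i], ]
    inf <- sub$collapsed[sub$category != "uninformative"]
    keys$n_informative[i] <- length(inf)
    if (length(inf) == 0) {
      keys$headline[i] <- "uninformative"
    } else {
      tab <- table(inf)
      top <- names(tab)[tab == max(tab)]
      keys$headline[i] <- top[which.min(restorative_rank[top])]
    }
  }
  rownames(keys) <- NULL
  keys
}

#' Group-level tests on restoration calls
#'
#' Two families of comparisons over the per-component calls: (1) for each
#' collapsed category, a Fisher exact test of category presence (a strain
#' shows the category on at least one component) between the 15 C and 43 C
#' assay conditions; (2) if a strain grouping is supplied (e.g. generalists
#' vs the rest), a one-sided Mann-Whitney test comparing the per-strain
#' number of components called in that category between the two groups. Both
#' reuse the package's shared test kernels.
#'
#' @param calls [classify_restoration()] output.
#' @param grouping optional named vector mapping `strain_id` to one of two
#'   group labels.
#' @param alternative direction for the Mann-Whitney comparisons (first group
#'   level vs second).
#' @param temperature optional filter (15 or 43) for the grouped comparisons.
#' @return data frame with `category`, `comparison`, `statistic`, `p_value`.
#' @export
restoration_group_tests <- function(calls, grouping = NULL,
                                    alternative = "greater",
                                    temperature = NULL) {
  cats <- setdiff(unique(collapse_restoration(restoration_categories)),
                  "uninformative")
  res <- list()
  strains <- unique(calls$strain_id)
  temps <- sort(unique(calls$temperature_C))
  if (length(temps) == 2) {
    for (cc in cats) {
      present <- vapply(temps, function(tm) {
        vapply(strains, function(s) any(
          calls$collapsed == cc & calls$strain_id == s &
            calls$temperature_C == tm), NA)
      }, logical(length(strains)))
      tab <- rbind(colSums(present), colSums(!present))
      res[[length(res) + 1L]] <- data.frame(
        category = cc, comparison = sprintf("%g_vs_%g", temps[1], temps[2]),
        statistic = NA_real_,
        p_value = fisher_strategy_enrichment(t(tab)))
    }
  }
  if (!is.null(grouping)) {
    if (is.null(names(grouping)) || !all(strains %in% names(grouping)))
      stop_config("grouping must cover every strain in the calls")
    g <- factor(grouping[strains])
    if (nlevels(g) != 2 || any(table(g) == 0))
      stop_config("grouping must define two non-empty groups")
    sub <- if (is.null(temperature)) calls else
      calls[calls$temperature_C == temperature, ]
    for (cc in cats) {
      counts <- vapply(strains, function(s)
        sum(sub$collapsed == cc & sub$strain_id == s), 0)
      mw <- class_count_compare(counts[g == levels(g)[1]],
                                counts[g == levels(g)[2]],
                                alternative = alternative)
      res[[length(res) + 1L]] <- data.frame(
        category = cc,
        comparison = sprintf("%s_vs_%s%s", levels(g)[1], levels(g)[2],
                             if (is.null(temperature)) "" else
                               sprintf("_at_%g", temperature)),
        statistic = mw$U, p_value = mw$p_value)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
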