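# Accept a named list of numeric vectors or an npi_dataset.
.as_groups <- function(groups) {
  if (inherits(groups, "npi_dataset")) groups <- groups$groups
  stopifnot(is.list(groups), length(groups) >= 2,
            !is.null(names(groups)), all(nzchar(names(groups))))
  lapply(groups, function(v) {
    stopifnot(is.numeric(v), length(v) >= 2, all(is.finite(v)))
    sort(v)
  })
}

#' Adjacent-group pairwise test outcomes
#'
#' Runs the `g - 1` upper-sided pooled-variance t-tests between adjacent
#' groups in the declared (dose) order: comparison `i` tests whether the
#' lower-dose group `i` exceeds the higher-dose group `i + 1`
#' (`H1: mu_L > mu_H`).  With `adjust = TRUE` the reject/not-reject decisions
#' use Benjamini-Hochberg adjusted p-values across the `g - 1` simultaneous
#' tests.
#'
#' @param groups Named list of numeric vectors in increasing dose order, or
#'   an `npi_dataset` from [read_long_csv()]/[load_fixture()].
#' @param alpha Significance level, default 0.05.
#' @param adjust Use BH-adjusted p-values for the decisions (default TRUE).
#' @return Object of class `"npi_outcomes"`: list with `outcome` (a Y/N
#'   string of length `g - 1`, Y = null rejected), `reject`, `p`,
#'   `p_adjusted`, `labels` and `comparisons`.
#' @examples
#' pairwise_outcomes(load_fixture("table1"))
#' @export
pairwise_outcomes <- function(groups, alpha = 0.05, adjust = TRUE) {
  g <- .as_groups(groups)
  labels <- names(g)
  k <- length(g) - 1
  p <- vapply(seq_len(k), function(i) {
    t_test_upper(g[[i]], g[[i + 1]], alpha = alpha)$p.value
  }, numeric(1))
  padj <- bh_adjust(p)
  rej <- (if (adjust) padj else p) < alpha
  structure(list(outcome = paste(ifelse(rej, "Y", "N"), collapse = ""),
                 reject = rej, p = p, p_adjusted = padj,
                 labels = labels, alpha = alpha, adjust = adjust,
                 comparisons = paste(labels[-length(labels)], "vs.",
                                     labels[-1])),
            class = "npi_outcomes")
}

#' @export
print.npi_outcomes <- function(x, ...) {
  cat("Adjacent pairwise comparisons (upper-sided pooled t):\n")
  for (i in seq_along(x$p)) {
    cat(sprintf("  %-10s p = %.4f  adj = %.4f  %s\n", x$comparisons[i],
                x$p[i], x$p_adjusted[i], if (x$reject[i]) "Y" else "N"))
  }
  cat("Outcome vector:", x$outcome, "\n")
  invisible(x)
}

#' Final dose decision from an outcome vector
#'
#' Selects the smallest dose whose comparison with the next larger dose
#' fails to reject the null: the lower-dose label of the first `N` in the
#' outcome vector, scanning from the control end.  If every comparison
#' rejects (`YY...Y`), the highest dose is returned — no comparison
#' certifies a plateau, so escalation runs to the end (configurable
#' convention via `all_reject`).
#'
#' @param outcome Y/N string of length `g - 1` (or an `npi_outcomes`).
#' @param labels Character vector of the `g` group labels in dose order.
#' @param all_reject Label returned when every symbol is Y; default the
#'   highest dose, `labels[g]`.
#' @return A single group label.
#' @examples
#' final_decision("YYYYN", LETTERS[1:6])  # "E"
#' final_decision("YYNYN", LETTERS[1:6])  # "C"
#' @export
final_decision <- function(outcome, labels, all_reject = labels[length(labels)]) {
  if (inherits(outcome, "npi_outcomes")) {
    if (missing(labels)) labels <- outcome$labels
    outcome <- outcome$outcome
  }
  syms <- strsplit(outcome, "")[[1]]
  stopifnot(all(syms %in% c("Y", "N")),
            length(syms) == length(labels) - 1)
  pos <- match("N", syms)
  if (is.na(pos)) all_reject else labels[pos]
}

#' Reproducibility of the final dose decision
#'
#' Computes the original adjacent-comparison outcome vector and decision,
#' then repeats the whole analysis on `N` NPI bootstrap replicates of the
#' study: each run draws one future sample per group (own maximum-gap
#' bounds, own size), performs the `g - 1` upper-sided t-tests with
#' (optional) BH adjustment at the same `alpha`, and records the Y/N outcome
#' vector.  The reproducibility of the decision (RPD) is the proportion of
#' runs whose outcome vector maps, through [final_decision()], to the same
#' dose as the original analysis.
#'
#' @inheritParams pairwise_outcomes
#' @param N Number of bootstrap runs, default 1000.
#' @param seed Optional integer seed.
#' @return Object of class `"npib_rpd"`: list with `rpd`, `table` (outcome
#'   frequency table, counts summing to `N`, descending with lexicographic
#'   tie-break), `original_outcome`, `original_decision`, `decision_map`,
#'   `original` (the `npi_outcomes`), and the configuration.
#' @examples
#' r <- rpd(load_fixture("table1"), N = 100, seed = 1)
#' r$rpd
#' @export
rpd <- function(groups, N = 1000, alpha = 0.05, adjust = TRUE, seed = NULL) {
  g <- .as_groups(groups)
  labels <- names(g)
  k <- length(g) - 1
  stopifnot(N >= 1)
  original <- pairwise_outcomes(g, alpha = alpha, adjust = adjust)
  original_decision <- final_decision(original$outcome, labels)

  prepared <- lapply(seq_along(g), function(i) {
    .prepare_sample(g[[i]], labels[i])
  })
  bounds <- lapply(prepared, npi_bounds)

  if (!is.null(seed)) set.seed(as.integer(seed))
  mats <- lapply(seq_along(prepared), function(i) {
    .npi_b_matrix(prepared[[i]], length(prepared[[i]]), N, bounds[[i]])
  })
  P <- vapply(seq_len(k), function(i) .t_p_rows(mats[[i]], mats[[i + 1]]),
              numeric(N))
  P <- matrix(P, nrow = N)
  if (adjust && k > 1) P <- t(apply(P, 1, p.adjust, method = "BH"))
  ch <- matrix(ifelse(P < alpha, "Y", "N"), nrow = N)
  vectors <- do.call(paste0, asplit(ch, 2))

  counts <- table(vectors)
  counts <- counts[order(-counts, names(counts))]
  tab <- as.integer(counts)
  names(tab) <- names(counts)
  decision_map <- vapply(names(tab), final_decision, character(1),
                         labels = labels)
  rpd_value <- sum(tab[decision_map == original_decision]) / N

  structure(list(rpd = rpd_value, table = tab,
                 original_outcome = original$outcome,
                 original_decision = original_decision,
                 decision_map = decision_map,
                 original = original, labels = labels,
                 N = N, alpha = alpha, adjust = adjust, seed = seed),
            class = "npib_rpd")
}

#' @export
print.npib_rpd <- function(x, ...) {
  cat(sprintf("Reproducibility of the final decision (N = %d runs)\n", x$N))
  cat(sprintf("  original outcome %s -> decision %s\n",
              x$original_outcome, x$original_decision))
  cat(sprintf("  RPD = %.3f\n", x$rpd))
  cat("  outcome frequency table:\n")
  for (i in seq_along(x$table)) {
    cat(sprintf("    %s  %4d  -> %s\n", names(x$table)[i], x$table[i],
                x$decision_map[i]))
  }
  invisible(x)
}

#' Shift measurements on the raw scale of log10 data
#'
#' Adds `delta` to the raw-scale values underlying log10-transformed
#' measurements: returns `log10(10^v + delta)` elementwise.  Used to
#' construct the modified dose column of the case study (raw values shifted
#' by 1.5 before the log transform).
#'
#' @param values Numeric vector of log10-scale measurements.
#' @param delta Raw-scale shift; every `10^v + delta` must stay positive.
#' @return Numeric vector on the log10 scale.
#' @examples
#' shift_on_raw_scale(0, 9)  # log10(1 + 9) = 1
#' @export
shift_on_raw_scale <- function(values, delta) {
  stopifnot(is.numeric(values), is.numeric(delta), length(delta) == 1)
  raw <- 10^values + delta
  if (any(raw <= 0)) stop("shift produces nonpositive raw values")
  log10(raw)
}

#' Outcome-frequency tree
#'
#' Arranges an outcome-vector frequency table as a binary tree splitting on
#' Y/N at each comparison depth.  Each node's weight is the summed count of
#' all observed vectors sharing its prefix; leaves are the observed vectors.
#'
#' @param table Named integer vector of outcome-vector counts (e.g. the
#'   `table` element of an [rpd()] result) or an `npib_rpd` object, in which
#'   case the branch leading to the original decision is highlighted.
#' @param highlight Optional character vector of outcome vectors whose
#'   leaves are marked with `*`.
#' @return Object of class `"npib_tree"`: list with `nodes` (data frame of
#'   `prefix`, `depth`, `count`) and `lines` (the rendered text tree).
#' @examples
#' r <- rpd(load_fixture("table1"), N = 50, seed = 1)
#' render_tree(r)
#' @export
render_tree <- function(table, highlight = NULL) {
  if (inherits(table, "npib_rpd")) {
    if (is.null(highlight)) {
      highlight <- names(table$table)[table$decision_map ==
                                        table$original_decision]
    }
    table <- table$table
  }
  stopifnot(length(table) >= 1, !is.null(names(table)), all(table >= 0))
  depth_max <- unique(nchar(names(table)))
  if (length(depth_max) != 1) stop("outcome vectors must share one length")

  prefix_count <- function(prefix) {
    sum(table[startsWith(names(table), prefix)])
  }
  nodes <- data.frame(prefix = "", depth = 0L, count = sum(table),
                      stringsAsFactors = FALSE)
  lines <- sprintf("runs %d", sum(table))
  recurse <- function(prefix, depth, indent) {
    for (sym in c("Y", "N")) {
      child <- paste0(prefix, sym)
      cnt <- prefix_count(child)
      if (cnt == 0 && !any(startsWith(names(table), child))) next
      pad <- strrep("·", depth_max - nchar(child))
      mark <- if (nchar(child) == depth_max && child %in% highlight) " *" else ""
      nodes <<- rbind(nodes, data.frame(prefix = child, depth = depth + 1L,
                                        count = cnt, stringsAsFactors = FALSE))
      lines <<- c(lines, sprintf("%s%s%s %d%s", indent, child, pad, cnt, mark))
      if (nchar(child) < depth_max) {
        recurse(child, depth + 1L, paste0(indent, "  "))
      }
    }
  }
  recurse("", 0L, "  ")
  structure(list(nodes = nodes, lines = lines, highlight = highlight),
            class = "npib_tree")
}

#' @export
print.npib_tree <- function(x, ...) {
  cat(x$lines, sep = "\n")
  if (length(x$highlight)) {
    cat("* leaf mapping to the original decision\n")
  }
  invisible(x)
}
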