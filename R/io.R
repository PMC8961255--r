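#' Read a long-format group/value table
#'
#' Reads a delimited file with header columns `group` and `value` (one
#' measurement per row).  Groups are ordered by first appearance in the
#' file — this declared order is the dose order used by the decision
#' functions — and values are sorted ascending within each group.
#'
#' @param path Path to a CSV file.
#' @param name Dataset name; defaults to the file name.
#' @return Object of class `"npi_dataset"`: list with `name`, `groups`
#'   (named list of sorted numeric vectors) and `provenance`.
#' @export
read_long_csv <- function(path, name = basename(path)) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("group", "value") %in% names(df))) {
    stop("input must have header columns 'group' and 'value'")
  }
  grp <- trimws(df$group)
  if (any(!nzchar(grp))) {
    stop("empty group label at row ", which(!nzchar(grp))[1])
  }
  val <- suppressWarnings(as.numeric(df$value))
  if (any(is.na(val))) {
    stop("non-numeric value at row ", which(is.na(val))[1])
  }
  labels <- unique(grp)
  groups <- lapply(labels, function(g) sort(val[grp == g]))
  names(groups) <- labels
  for (g in labels) {
    if (anyDuplicated(groups[[g]])) {
      message("note: tied values in group ", g)
    }
  }
  structure(list(name = name, groups = groups,
                 provenance = paste("read from", path)),
            class = "npi_dataset")
}

#' Write a dataset back to long-format CSV
#'
#' @param dataset An `npi_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_long_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "npi_dataset"))
  df <- data.frame(
    group = rep(names(dataset$groups), lengths(dataset$groups)),
    value = unlist(dataset$groups, use.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.npi_dataset <- function(x, ...) {
  cat(sprintf("npi_dataset '%s': %d groups (%s)\n", x$name,
              length(x$groups),
              paste(sprintf("%s n=%d", names(x$groups),
                            lengths(x$groups)), collapse = ", ")))
  invisible(x)
}

#' Bundled dose-response case-study data
#'
#' Log10-transformed measurements for six increasing drug concentrations:
#' control A and doses B-F (lower values mean the drug performs better).
#' `"table1"` returns the original groups A-F; `"table1_dprime"` substitutes
#' the modified column D' — the dose-D measurements shifted by +1.5 on the
#' raw scale before the log transform — for D.
#'
#' @param name `"table1"` or `"table1_dprime"`.
#' @return An `npi_dataset` with six groups in dose order.
#' @examples
#' load_fixture("table1")
#' @export
load_fixture <- function(name = c("table1", "table1_dprime")) {
  name <- match.arg(name)
  path <- system.file("extdata", "table1.csv", package = "npirep",
                      mustWork = TRUE)
  ds <- read_long_csv(path, name = name)
  g <- ds$groups
  if (name == "table1") {
    g <- g[c("A", "B", "C", "D", "E", "F")]
  } else {
    g <- g[c("A", "B", "C", "Dprime", "E", "F")]
    names(g)[4] <- "D'"
  }
  structure(list(name = name, groups = g,
                 provenance = "bundled dose-response case study (log10 scale)"),
            class = "npi_dataset")
}

#' Write an analysis report
#'
#' Serialises a result from [npi_b_rp()], [rpd()] or [run_study()].
#' JSON reports carry the configuration, seed and package version alongside
#' the results; the CSV format for a decision result is the two-column
#' outcome/count frequency table; the text format is the printed summary
#' (for a decision result, the outcome tree).
#'
#' @param result An `npib_rp`, `npib_rpd` or `run_study()` data frame.
#' @param path Output file path.
#' @param format `"json"`, `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "csv", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- .report_payload(result)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else if (format == "csv") {
    if (inherits(result, "npib_rpd")) {
      df <- data.frame(outcome = names(result$table),
                       count = as.integer(result$table))
    } else if (inherits(result, "npib_rp")) {
      df <- data.frame(run = seq_along(result$rp), rp = result$rp)
    } else if (is.data.frame(result)) {
      df <- result
    } else {
      stop("no CSV representation for this result")
    }
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    lines <- if (inherits(result, "npib_rpd")) {
      c(utils::capture.output(print(result)), "",
        render_tree(result)$lines)
    } else {
      utils::capture.output(print(result))
    }
    writeLines(lines, path)
  }
  invisible(path)
}

.report_payload <- function(result) {
  meta <- list(package = "npirep",
               version = as.character(packageVersion("npirep")))
  if (inherits(result, "npib_rp")) {
    hist <- table(cut(result$rp, breaks = seq(0, 1, by = 0.05),
                      include.lowest = TRUE))
    c(meta, list(
      type = "npi_b_rp",
      config = list(test = result$test, alpha = result$alpha, N = result$N,
                    h = result$h, m_x = result$m_x, m_y = result$m_y,
                    seed = result$seed),
      original = list(statistic = result$original$statistic,
                      p_value = result$original$p.value,
                      reject = result$original$reject,
                      effect_size = result$original_stats$effect_size,
                      cohens_d = result$original_stats$cohens_d),
      rp_min = result$rp_min, rp_mean = result$rp_mean,
      rp_max = result$rp_max, rp_values = result$rp,
      rp_histogram = as.list(hist)))
  } else if (inherits(result, "npib_rpd")) {
    c(meta, list(
      type = "rpd",
      config = list(alpha = result$alpha, N = result$N,
                    adjust = result$adjust, seed = result$seed),
      original_outcome = result$original_outcome,
      original_decision = result$original_decision,
      p_raw = result$original$p,
      p_adjusted = result$original$p_adjusted,
      rpd = result$rpd,
      frequency_table = as.list(result$table),
      decision_map = as.list(result$decision_map)))
  } else if (is.data.frame(result)) {
    c(meta, list(type = "simulation", records = result))
  } else {
    stop("unsupported result type")
  }
}
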