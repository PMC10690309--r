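#' Load a bundled published confusion-matrix fixture
#'
#' The package ships verbatim transcriptions of three published k-class
#' confusion matrices from an ex-vivo renal OCT study (rows = true class,
#' 10,000 images per class): the 5-class attenuation-coefficient matrix
#' (`"table1a"`, pelvis excluded because its attenuation is not computable)
#' and the two 6-class CNN matrices (`"table2a"`, `"table2b"`).
#'
#' @param name One of `"table1a"`, `"table2a"`, `"table2b"`.
#' @return A `confusion_matrix`.
#' @examples
#' cm <- oct_table_fixture("table1a")
#' one_vs_rest(cm, "tumor")
#' @export
oct_table_fixture <- function(name = c("table1a", "table2a", "table2b")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "octatten")
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  as_confusion_matrix(m)
}

#' The published per-class metric values, as printed
#'
#' @return data.frame with columns `table`, `class`, `metric`,
#'   `printed_pct`.
#' @export
printed_metrics <- function() {
  utils::read.csv(system.file("extdata", "printed_metrics.csv",
                              package = "octatten"),
                  stringsAsFactors = FALSE)
}

#' Recompute every published metric from the bundled confusion matrices
#'
#' For each printed per-class value, recomputes the quantity from the
#' transcribed integer counts (one-vs-rest on the full pooled matrix;
#' `as_tumor_rate` is the class row's tumor-column count over the row
#' total) and compares with the printed number at printed precision: a
#' 2-decimal percentage represents its value to within half a printed unit,
#' so agreement means `|computed - printed| <= 0.005`.
#'
#' @return Object of class `printed_metrics_check`: data.frame with
#'   columns `table`, `class`, `metric`, `printed_pct`, `computed_pct`,
#'   `diff`, `match`.
#' @examples
#' chk <- reproduce_printed_metrics()
#' all(chk$match)
#' @export
reproduce_printed_metrics <- function() {
  golden <- printed_metrics()
  golden$computed_pct <- NA_real_
  for (tab in unique(golden$table)) {
    cm <- oct_table_fixture(tab)
    rep <- metrics_report(cm)
    sel <- golden$table == tab
    for (i in which(sel)) {
      cl <- golden$class[i]; met <- golden$metric[i]
      golden$computed_pct[i] <- if (met == "as_tumor_rate") {
        m <- unclass(cm)
        100 * m[cl, "tumor"] / sum(m[cl, ])
      } else {
        100 * rep[[met]][rep$class == cl]
      }
    }
  }
  golden$diff <- golden$computed_pct - golden$printed_pct
  golden$match <- abs(golden$diff) <= 0.005 + 1e-9
  class(golden) <- c("printed_metrics_check", "data.frame")
  golden
}

#' @export
print.printed_metrics_check <- function(x, ...) {
  n_bad <- sum(!x$match)
  cat(sprintf("Published-metric reproduction: %d/%d values match at printed precision\n",
              sum(x$match), nrow(x)))
  if (n_bad > 0) {
    cat("mismatches:\n")
    print.data.frame(x[!x$match, ], row.names = FALSE, digits = 6)
  }
  invisible(x)
}
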