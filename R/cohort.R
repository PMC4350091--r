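#' Case-control cohort
#'
#' A cohort is a data frame with one row per sample: a unique `sample`
#' id, a `status` factor with levels `control`/`case`, and an integer
#' `age` in years (used only as a regression covariate).
#'
#' @param sample character vector of unique sample ids.
#' @param status case/control labels; anything matching "case"/"control"
#'   case-insensitively is accepted.
#' @param age numeric ages in years.
#' @return a `cohort` data frame.
#' @export
cohort <- function(sample, status, age) {
  sample <- as.character(sample)
  if (anyDuplicated(sample))
    stopf("duplicated sample id(s): %s",
          paste(unique(sample[duplicated(sample)]), collapse = ", "))
  st <- tolower(as.character(status))
  bad <- !st %in% c("case", "control")
  if (any(bad))
    stopf("unknown status label(s): %s",
          paste(unique(status[bad]), collapse = ", "))
  if (length(st) != length(sample) || length(age) != length(sample))
    stopf("sample, status and age must have equal lengths")
  out <- data.frame(sample = sample,
                    status = factor(st, levels = c("control", "case")),
                    age = as.numeric(age),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort", "data.frame")
  out
}

is_case <- function(ch) ch$status == "case"

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples: %d cases, %d controls\n",
              nrow(x), sum(is_case(x)), sum(!is_case(x))))
  invisible(x)
}

#' Read a phenotype table
#'
#' Expects a tab-separated file with header columns `sample`, `status`
#' and `age`. Status labels are matched case-insensitively.
#'
#' @param path path to the TSV file.
#' @return a [cohort()].
#' @export
read_phenotypes <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = "sample"),
                          data.table = FALSE)
  need <- c("sample", "status", "age")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("phenotype file %s lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  cohort(df$sample, df$status, df$age)
}

#' Write a phenotype table
#' @param ch a [cohort()].
#' @param path output TSV path.
#' @export
write_phenotypes <- function(ch, path) {
  data.table::fwrite(as.data.frame(ch), path, sep = "\t")
  invisible(path)
}
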