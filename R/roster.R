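#' Generate the study cohort roster
#'
#' Deterministic roster of 933 retrospective cases: 460 females and 473 males,
#' with exclusion flags (hip prosthesis, knee prosthesis, osteosynthesis
#' material, segmentation/registration error) distributed per sex exactly as
#' tallied in the source cohort. Flags are mutually exclusive per record so
#' per-reason tallies sum exactly.
#'
#' @return data frame with columns `case_id`, `sex`, `hip_prosthesis`,
#'   `knee_prosthesis`, `osteosynthesis`, `segmentation_error`.
#' @export
generate_roster <- function() {
  build <- function(sex, total, hip, knee, osteo, segerr) {
    flags <- matrix(FALSE, total, 4)
    idx <- 1L
    for (j in seq_along(c(hip, knee, osteo, segerr))) {
      n <- c(hip, knee, osteo, segerr)[j]
      if (n > 0) flags[idx:(idx + n - 1L), j] <- TRUE
      idx <- idx + n
    }
    data.frame(sex = sex, hip_prosthesis = flags[, 1], knee_prosthesis = flags[, 2],
               osteosynthesis = flags[, 3], segmentation_error = flags[, 4])
  }
  df <- rbind(build("female", 460L, 40L, 5L, 2L, 14L),
              build("male", 473L, 42L, 5L, 15L, 12L))
  df <- cbind(case_id = sprintf("case_%04d", seq_len(nrow(df))), df)
  df
}

#' Apply the cohort exclusion criteria
#'
#' Excludes every record with any exclusion flag set (arthroplasty at hip or
#' knee, osteosynthesis material, segmentation/registration error) and tallies
#' exclusions per reason per sex.
#'
#' @param roster data frame as from [generate_roster()].
#' @return list with `included` (data frame of retained records), `counts`
#'   (per-reason, per-sex exclusion counts), `n_included`, `n_excluded`.
#' @export
apply_exclusions <- function(roster) {
  reasons <- c("hip_prosthesis", "knee_prosthesis", "osteosynthesis",
               "segmentation_error")
  stopifnot(all(c("sex", reasons) %in% names(roster)))
  if (nrow(roster) == 0L) {
    counts <- as.data.frame(matrix(0L, 0, length(reasons),
                                   dimnames = list(NULL, reasons)))
    return(list(included = roster, counts = counts, n_included = 0L,
                n_excluded = 0L))
  }
  flagged <- Reduce(`|`, roster[reasons])
  counts <- do.call(rbind, lapply(split(roster, roster$sex), function(d) {
    c(vapply(reasons, function(r) sum(d[[r]]), 0L),
      excluded = sum(Reduce(`|`, d[reasons])), total = nrow(d))
  }))
  list(included = roster[!flagged, , drop = FALSE],
       counts = as.data.frame(counts),
       n_included = sum(!flagged), n_excluded = sum(flagged))
}

#' Write / read a roster CSV
#'
#' @param roster data frame as from [generate_roster()].
#' @param path file path.
#' @export
write_roster_csv <- function(roster, path) {
  utils::write.csv(roster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("hip_prosthesis", "knee_prosthesis", "osteosynthesis",
                "segmentation_error"))
    df[[col]] <- as.logical(df[[col]])
  df
}
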