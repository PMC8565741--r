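#' Read a sample-by-feature abundance table
#'
#' Tab-delimited text, first column sample identifiers, header row of
#' feature labels.  All cells must be numeric and complete: missing values
#' must be imputed upstream (e.g. k-nearest-neighbour imputation) before
#' testing.
#'
#' @param path File path.
#' @param delim Field delimiter (default tab).
#' @return A tibble with `sample_id` first and one numeric column per
#'   feature (the format [kat_test()] accepts).
#' @export
read_feature_table <- function(path, delim = "\t") {
  raw <- utils::read.delim(path, sep = delim, header = TRUE,
                           check.names = FALSE, colClasses = "character")
  if (nrow(raw) == 0L) stop("no data rows in '", path, "'")
  if (ncol(raw) < 2L) stop("expected a sample-id column plus feature columns")
  ids <- raw[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- raw
  for (j in seq_along(raw)[-1L]) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad)) {
      stop("non-numeric or missing value at row ", bad[1L], ", column '",
           names(raw)[j], "' of '", path,
           "'; impute missing values upstream")
    }
    out[[j]] <- v
  }
  names(out)[1L] <- "sample_id"
  tibble::as_tibble(out)
}

#' Write a delimited table
#'
#' Tab-delimited, no quoting, no row names; numerics keep full precision so
#' write/read round-trips are lossless at 12+ significant digits.
#'
#' @param x Data frame.
#' @param path Output path.
#' @export
write_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read pathway definitions from GMT plus an edge list
#'
#' GMT supplies membership and node order (one pathway per line: name,
#' description, then tab-separated member labels).  The optional edge file
#' is tab-delimited with three columns `pathway_id  node_u  node_v` and an
#' optional header line; edges referencing a non-member are dropped with a
#' warning.  Without an edge file every pathway is edgeless.
#'
#' @param gmt_path Path to the GMT file.
#' @param edges_path Optional path to the edge list.
#' @return A tibble of class `kat_pathways` with columns `pathway_id`,
#'   `description`, `n_members`, `members` (list), `edges` (list of
#'   two-column character matrices), and `flagged_small` (fewer than two
#'   members).
#' @export
read_pathways <- function(gmt_path, edges_path = NULL) {
  lines <- readLines(gmt_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file '", gmt_path, "'")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop("malformed GMT line ", short[1L], " in '", gmt_path,
         "': fewer than 3 tab-separated fields")
  }
  pw <- tibble::tibble(
    pathway_id = vapply(parts, `[[`, character(1L), 1L),
    description = vapply(parts, `[[`, character(1L), 2L),
    members = lapply(parts, function(f) unique(f[-(1:2)])))
  if (anyDuplicated(pw$pathway_id)) {
    stop("duplicate pathway id(s) in GMT: ",
         paste(unique(pw$pathway_id[duplicated(pw$pathway_id)]),
               collapse = ", "))
  }
  pw$n_members <- lengths(pw$members)

  edges <- rep(list(matrix(character(0), ncol = 2L)), nrow(pw))
  if (!is.null(edges_path)) {
    ef <- utils::read.delim(edges_path, header = FALSE, sep = "\t",
                            colClasses = "character")
    if (ncol(ef) != 3L) {
      stop("edge file must have 3 tab-separated columns: pathway_id, node_u, node_v")
    }
    if (nrow(ef) && tolower(ef[1L, 1L]) %in% c("pathway_id", "pathway")) {
      ef <- ef[-1L, , drop = FALSE]
    }
    unknown_pw <- !ef[[1L]] %in% pw$pathway_id
    if (any(unknown_pw)) {
      warning(sum(unknown_pw), " edge(s) reference unknown pathway ids; dropped")
      ef <- ef[!unknown_pw, , drop = FALSE]
    }
    dropped <- 0L
    for (i in seq_len(nrow(pw))) {
      sub <- ef[ef[[1L]] == pw$pathway_id[i], , drop = FALSE]
      if (!nrow(sub)) next
      mem <- pw$members[[i]]
      okr <- sub[[2L]] %in% mem & sub[[3L]] %in% mem
      dropped <- dropped + sum(!okr)
      if (any(okr)) {
        edges[[i]] <- cbind(sub[[2L]][okr], sub[[3L]][okr])
      }
    }
    if (dropped) {
      warning(dropped, " edge(s) referenced labels outside their pathway's ",
              "member list; dropped")
    }
  }
  pw$edges <- edges
  pw$flagged_small <- pw$n_members < 2L
  if (any(pw$flagged_small)) {
    warning(sum(pw$flagged_small),
            " pathway(s) have fewer than 2 members and will be skipped by kat_test()")
  }
  pw <- pw[, c("pathway_id", "description", "n_members", "members",
               "edges", "flagged_small")]
  class(pw) <- c("kat_pathways", class(pw))
  pw
}
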