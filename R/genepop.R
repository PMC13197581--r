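#' Read a GENEPOP file into a long genotype tibble
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per line
#' (or a single comma-separated line), `POP` separators, then per-sample rows
#' of the form `id , a1a2 a1a2 ...` with `allele_digits` digits per allele.
#' An all-zero call (`0000` / `000000`) marks a missing locus.
#'
#' The long genotype tibble is the canonical exchange format of this
#' package: one row per sample x locus with columns `sample_id`, `site`,
#' `quadrat`, `locus`, `allele_1`, `allele_2`.  Allele order within a locus
#' carries no meaning; missing loci have both alleles `NA`.
#'
#' @param path path to a GENEPOP file.
#' @param allele_digits digits per allele, 2 or 3.
#' @param site_names optional character vector naming the POP blocks in
#'   order; by default each block is named after its first sample id.
#' @return a tibble with columns `sample_id`, `site`, `quadrat`, `locus`,
#'   `allele_1`, `allele_2`.
#' @seealso [write_genepop()], [read_genotypes_csv()]
#' @export
read_genepop <- function(path, allele_digits = 3, site_names = NULL) {
  stopifnot(allele_digits %in% c(2, 3))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines)]
  if (length(lines) < 3) stop("not a GENEPOP file: too few lines.", call. = FALSE)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1]
  if (is.na(first_pop)) stop("not a GENEPOP file: no POP separator.", call. = FALSE)
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (length(loci) == 0) stop("no locus names found.", call. = FALSE)

  block <- cumsum(is_pop)
  body <- which(!is_pop & seq_along(lines) > first_pop)
  n_pops <- max(block)
  if (!is.null(site_names) && length(site_names) != n_pops) {
    stop("`site_names` must have one name per POP block (", n_pops, ").",
         call. = FALSE)
  }

  rows <- vector("list", length(body))
  pop_first_id <- character(n_pops)
  for (k in seq_along(body)) {
    i <- body[k]
    parts <- strsplit(lines[i], ",")[[1]]
    if (length(parts) < 2) {
      stop("line ", i, ": expected 'id , calls' with a comma.", call. = FALSE)
    }
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(calls) != length(loci)) {
      stop("line ", i, ": ", length(calls), " genotype calls but ",
           length(loci), " loci declared.", call. = FALSE)
    }
    if (any(nchar(calls) != 2 * allele_digits)) {
      bad <- calls[nchar(calls) != 2 * allele_digits][1]
      stop("line ", i, ": call '", bad, "' is not ", 2 * allele_digits,
           " digits.", call. = FALSE)
    }
    a1 <- as.integer(substr(calls, 1, allele_digits))
    a2 <- as.integer(substr(calls, allele_digits + 1, 2 * allele_digits))
    miss <- a1 == 0 | a2 == 0
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    b <- block[i]
    if (pop_first_id[b] == "") pop_first_id[b] <- id
    rows[[k]] <- tibble::tibble(
      sample_id = id, pop = b, locus = loci, allele_1 = a1, allele_2 = a2
    )
  }
  out <- dplyr::bind_rows(rows)
  labels <- if (is.null(site_names)) pop_first_id else site_names
  out <- dplyr::mutate(out,
    site = labels[.data$pop], quadrat = NA_character_, pop = NULL)
  dup <- out |>
    dplyr::distinct(.data$sample_id, .data$site) |>
    dplyr::count(.data$sample_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    # same id reused across POP blocks: disambiguate so sample_id stays unique
    out <- dplyr::mutate(out, sample_id = ifelse(
      .data$sample_id %in% dup$sample_id,
      paste(.data$site, .data$sample_id, sep = ":"), .data$sample_id))
  }
  dplyr::select(out, "sample_id", "site", "quadrat", "locus",
                "allele_1", "allele_2")
}

#' Write a long genotype tibble as a GENEPOP file
#'
#' @param genotypes a long genotype tibble (see [read_genepop()]).
#' @param path output path.
#' @param allele_digits digits per allele, 2 or 3.
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(genotypes, path, allele_digits = 3,
                          title = "clonescape export") {
  check_genotypes(genotypes)
  loci <- unique(genotypes$locus)
  fmt <- function(a) {
    a[is.na(a)] <- 0
    sprintf(paste0("%0", allele_digits, "d"), a)
  }
  if (any(stats::na.omit(c(genotypes$allele_1, genotypes$allele_2)) >=
          10^allele_digits)) {
    stop("allele sizes do not fit in ", allele_digits, " digits.",
         call. = FALSE)
  }
  wide <- genotypes |>
    dplyr::mutate(call = paste0(fmt(.data$allele_1), fmt(.data$allele_2))) |>
    dplyr::select("sample_id", "site", "locus", "call") |>
    tidyr::pivot_wider(names_from = "locus", values_from = "call")
  lines <- c(title, loci)
  for (s in unique(wide$site)) {
    lines <- c(lines, "POP")
    rows <- wide[wide$site == s, , drop = FALSE]
    lines <- c(lines, paste0(rows$sample_id, " , ",
      apply(rows[, loci, drop = FALSE], 1, paste, collapse = " ")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a long-format CSV
#'
#' Columns: `sample`, `site`, `quadrat` (optional), `locus`, `allele1`,
#' `allele2`.  Missing loci may be blank or 0.
#'
#' @param path CSV path.
#' @return a long genotype tibble (see [read_genepop()]).
#' @export
read_genotypes_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  need <- c("sample", "site", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("CSV must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(
    sample_id = as.character(df$sample),
    site = as.character(df$site),
    quadrat = if ("quadrat" %in% names(df)) as.character(df$quadrat)
              else NA_character_,
    locus = as.character(df$locus),
    allele_1 = as.integer(df$allele1),
    allele_2 = as.integer(df$allele2)
  )
  miss <- is.na(out$allele_1) | is.na(out$allele_2) |
    out$allele_1 == 0 | out$allele_2 == 0
  out$allele_1[miss] <- NA_integer_
  out$allele_2[miss] <- NA_integer_
  check_genotypes(out)
  out
}

# Validate the long genotype tibble contract: required columns, a locus is
# fully called or fully missing, fixed locus set across samples.
check_genotypes <- function(genotypes) {
  need <- c("sample_id", "site", "locus", "allele_1", "allele_2")
  if (!all(need %in% names(genotypes))) {
    stop("genotype tibble must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  half <- xor(is.na(genotypes$allele_1), is.na(genotypes$allele_2))
  if (any(half)) {
    stop("a locus must be fully called or fully missing; half-called rows ",
         "found.", call. = FALSE)
  }
  counts <- genotypes |>
    dplyr::count(.data$sample_id, name = "n_loci") |>
    dplyr::distinct(.data$n_loci)
  if (nrow(counts) > 1) {
    stop("inconsistent locus counts across samples.", call. = FALSE)
  }
  invisible(genotypes)
}
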