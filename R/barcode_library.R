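#' Read a guide barcode library
#'
#' Loads a CSV/TSV table of CRISPR guides (`guide_id`, `gene`, spacer
#' column) and derives the detection sequence of every entry as the reverse
#' complement of its spacer — the strand actually read out by in situ
#' sequencing of the barcode amplicon.
#'
#' Entries whose spacer contains characters outside A/C/G/T are dropped
#' with a warning. Entries sharing an identical spacer are kept but flagged
#' `duplicate`; downstream matching treats hits to such groups as
#' ambiguous.
#'
#' @param path Path to a delimited table with a header. Comma and tab
#'   delimiters are auto-detected.
#' @param spacer_column Name of the column holding the spacer sequence
#'   (default `"spacer"`).
#' @return A `barcode_library`: a tibble with columns `guide_id`, `gene`,
#'   `spacer`, `detect_seq`, `duplicate`, carrying attribute
#'   `is_scrambled = FALSE`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("guide_id,gene,spacer",
#'              "g1,TP53,GTTTACGTGTTTACGTACGT",
#'              "g2,NT,ACGTACGTACGTACGTACGT"), tf)
#' lib <- read_barcode_library(tf)
#' lib$detect_seq
#' @export
read_barcode_library <- function(path, spacer_column = "spacer") {
  tab <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE,
                           delim = if (grepl("\\.tsv$", path)) "\t" else ",")
  need <- c("guide_id", "gene", spacer_column)
  if (!all(need %in% names(tab))) {
    stop("library table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab <- dplyr::rename(tab, spacer = dplyr::all_of(spacer_column))
  barcode_library(tab)
}

#' Construct a barcode library from a data frame
#'
#' @param entries Data frame with `guide_id`, `gene`, `spacer` columns.
#' @return A `barcode_library` tibble (see [read_barcode_library()]).
#' @export
barcode_library <- function(entries) {
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0L) stop("no entries in barcode library", call. = FALSE)
  entries$spacer <- toupper(entries$spacer)
  bad <- grepl("[^ACGT]", entries$spacer)
  if (any(bad)) {
    warning(sum(bad), " entr", if (sum(bad) == 1L) "y" else "ies",
            " with non-ACGT characters dropped: ",
            paste(utils::head(entries$guide_id[bad], 5L), collapse = ", "),
            call. = FALSE)
    entries <- entries[!bad, , drop = FALSE]
  }
  if (nrow(entries) == 0L) stop("no entries in barcode library", call. = FALSE)
  if (anyDuplicated(entries$guide_id)) {
    stop("duplicate guide_id in library", call. = FALSE)
  }
  if (length(unique(nchar(entries$spacer))) != 1L) {
    stop("all spacers must have the same length", call. = FALSE)
  }
  entries$detect_seq <- revcomp(entries$spacer)
  entries$duplicate <- duplicated(entries$spacer) |
    duplicated(entries$spacer, fromLast = TRUE)
  if (any(entries$duplicate)) {
    warning(sum(entries$duplicate), " entries share a spacer with another ",
            "entry; flagged as ambiguous", call. = FALSE)
  }
  out <- dplyr::select(entries, "guide_id", "gene", "spacer", "detect_seq",
                       "duplicate", dplyr::everything())
  attr(out, "is_scrambled") <- FALSE
  class(out) <- c("barcode_library", class(out))
  out
}

#' Reverse complement of DNA sequences
#'
#' @param x Character vector over the A/C/G/T alphabet.
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("GTTTACGT")
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(s) paste(rev(s), collapse = ""), character(1))
}

#' Scramble a barcode library
#'
#' Replaces every detection sequence by a seeded random permutation of its
#' own characters, preserving each sequence's base composition. Matching
#' real reads against the scrambled library measures the chance-level
#' mapping rate, the negative control for barcode-call specificity.
#'
#' @param lib A `barcode_library`.
#' @param seed Integer seed; the same seed always yields the same
#'   scrambled library.
#' @param per_sequence Permute each sequence independently (default). With
#'   `FALSE` all detection sequences are drawn from one pooled, shuffled
#'   base reservoir, preserving only the library-wide composition.
#' @return A `barcode_library` with `is_scrambled = TRUE`.
#' @export
scramble_library <- function(lib, seed, per_sequence = TRUE) {
  stopifnot(inherits(lib, "barcode_library"), nrow(lib) >= 1L)
  chars <- strsplit(lib$detect_seq, "", fixed = TRUE)
  out <- lib
  scrambled <- with_seed_compat(seed, {
    if (per_sequence) {
      vapply(chars, function(s) paste(sample(s), collapse = ""), character(1))
    } else {
      pool <- sample(unlist(chars))
      lens <- lengths(chars)
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      vapply(seq_along(lens), function(i) {
        paste(pool[starts[i]:ends[i]], collapse = "")
      }, character(1))
    }
  })
  out$detect_seq <- scrambled
  attr(out, "is_scrambled") <- TRUE
  attr(out, "scramble_seed") <- as.integer(seed)
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed_compat <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @export
print.barcode_library <- function(x, ...) {
  cat(sprintf("<barcode_library: %d guides, %d genes, L = %d%s>\n",
              nrow(x), length(unique(x$gene)), nchar(x$spacer[1]),
              if (isTRUE(attr(x, "is_scrambled"))) ", scrambled" else ""))
  NextMethod()
}
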