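#' @useDynLib paleotip, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## Character matrices are stored as integer bitmask matrices: cell (t, c)
## has bit j set iff state j is compatible with the observation. A missing
## entry ("?" or "-") carries the full alphabet of its character; a
## polymorphism "(ab)"/"{ab}" carries exactly the listed states. The
## per-character alphabet is {0, ..., max observed state}.

#' Construct a character matrix
#'
#' Builds the container shared by every stage of the pipeline: an ordered
#' taxon list plus, for each (taxon, character) cell, a non-empty set of
#' integer states encoded as a bitmask. Polymorphic and missing entries are
#' both represented as uncertainty sets; a missing cell is simply the full
#' alphabet of its character.
#'
#' @param taxa character vector of unique taxon labels (spaces are replaced
#'   by underscores).
#' @param masks integer matrix, taxa x characters, of state bitmasks
#'   (bit \code{j} = state \code{j} present). Every entry must be positive.
#' @return an object of class \code{char_matrix} with elements \code{taxa},
#'   \code{masks}, \code{n_char}, \code{n_states} (per-character alphabet
#'   size) and \code{n_taxa}.
#' @export
char_matrix <- function(taxa, masks) {
  taxa <- normalize_labels(taxa)
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon labels: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  masks <- as.matrix(masks)
  storage.mode(masks) <- "integer"
  if (nrow(masks) != length(taxa)) stop("masks rows must match taxa")
  if (any(masks <= 0L)) stop("every cell must allow at least one state")
  n_states <- apply(masks, 2L, function(col) max_bit(col))
  ## missing cells written before the alphabet is known get clipped to it
  for (j in seq_len(ncol(masks))) {
    full <- bitwShiftL(1L, n_states[j]) - 1L
    masks[, j] <- bitwAnd(masks[, j], full)
  }
  rownames(masks) <- taxa
  structure(
    list(taxa = taxa, masks = masks, n_char = ncol(masks),
         n_taxa = length(taxa), n_states = as.integer(n_states)),
    class = "char_matrix")
}

normalize_labels <- function(x) gsub(" ", "_", trimws(x))

max_bit <- function(masks) {
  m <- max(masks)
  n <- 0L
  while (bitwShiftL(1L, n) <= m) n <- n + 1L
  n
}

#' @export
print.char_matrix <- function(x, ...) {
  cat(sprintf("char_matrix: %d taxa x %d characters\n", x$n_taxa, x$n_char))
  cat(sprintf("  state counts: %s\n",
              paste(names(tb <- table(x$n_states)), "states:", tb,
                    collapse = "; ")))
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) c(x$n_taxa, x$n_char)

#' States present in one cell
#'
#' @param x a \code{char_matrix}.
#' @param taxon taxon label or index.
#' @param char character index.
#' @return integer vector of states (0-based) compatible with the cell.
#' @export
cell_states <- function(x, taxon, char) {
  mask_to_states(x$masks[taxon, char])
}

mask_to_states <- function(mask) {
  which(bitwAnd(mask, bitwShiftL(1L, 0:30)) != 0L) - 1L
}

states_to_mask <- function(states) {
  sum(bitwShiftL(1L, as.integer(states)))
}

## ---- parsing ---------------------------------------------------------------

#' Read a NEXUS standard-datatype morphological matrix
#'
#' Parses the DATA or CHARACTERS block of a NEXUS file with
#' \code{DATATYPE=STANDARD}. \code{?} and the gap symbol map to the full
#' per-character alphabet; \code{(ab)} and \code{\{ab\}} map to the state set
#' \{a, b\}. Interleaved matrices and quoted taxon labels are supported.
#'
#' @param path path to a NEXUS file.
#' @return a \code{char_matrix}.
#' @export
parse_nexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) {
    stop("not a NEXUS file (missing #NEXUS header): ", path)
  }
  ## strip comments [...] (not nested in practice for data blocks)
  txt <- gsub("\\[[^]]*\\]", "", txt)
  block <- extract_block(txt, c("data", "characters"))
  if (is.null(block)) stop("no DATA or CHARACTERS block found in ", path)

  ntax <- nexus_number(block, "ntax")
  nchar_ <- nexus_number(block, "nchar")
  if (is.na(ntax) || is.na(nchar_)) stop("DIMENSIONS must declare NTAX and NCHAR")
  fmt <- nexus_command(block, "format")
  if (!is.null(fmt) && !grepl("datatype\\s*=\\s*standard", fmt, ignore.case = TRUE)) {
    stop("only DATATYPE=STANDARD matrices are supported")
  }
  missing_sym <- nexus_option(fmt, "missing", "?")
  gap_sym <- nexus_option(fmt, "gap", "-")
  symbols <- nexus_option(fmt, "symbols", NULL)
  allowed <- if (is.null(symbols)) NULL else {
    s <- gsub("[\" ]", "", symbols)
    strsplit(s, "")[[1]]
  }

  mat_txt <- sub("(?is).*?\\bmatrix\\b(.*?);.*", "\\1", block, perl = TRUE)
  if (identical(mat_txt, block)) stop("malformed MATRIX command (missing ';')")
  rows <- strsplit(mat_txt, "\n")[[1]]
  rows <- rows[trimws(rows) != ""]

  taxa <- character(0)
  cells <- list()
  for (row in rows) {
    parsed <- parse_matrix_row(row, missing_sym, gap_sym, allowed)
    if (is.null(parsed)) next
    tx <- parsed$taxon
    if (tx %in% taxa) {
      cells[[tx]] <- c(cells[[tx]], parsed$states)  # interleaved continuation
    } else {
      taxa <- c(taxa, tx)
      cells[[tx]] <- parsed$states
    }
  }
  if (length(taxa) != ntax) {
    stop(sprintf("declared NTAX=%d but matrix has %d taxa", ntax, length(taxa)))
  }
  lens <- vapply(cells, length, 1L)
  if (any(lens != nchar_)) {
    bad <- taxa[lens != nchar_][1L]
    stop(sprintf("taxon '%s' has %d characters, declared NCHAR=%d",
                 bad, lens[[bad]], nchar_))
  }

  ## resolve missing markers (coded as -1) to full alphabet per character
  raw <- do.call(rbind, cells[taxa])
  masks <- matrix(0L, length(taxa), nchar_)
  for (j in seq_len(nchar_)) {
    col <- raw[, j]
    obs <- col[col > 0L]
    ns <- if (length(obs)) max_bit(obs) else 1L
    full <- bitwShiftL(1L, ns) - 1L
    col[col < 0L] <- full
    masks[, j] <- col
  }
  char_matrix(taxa, masks)
}

extract_block <- function(txt, names) {
  for (nm in names) {
    m <- regmatches(txt, regexpr(
      paste0("(?is)\\bbegin\\s+", nm, "\\s*;.*?\\bend\\s*;"), txt, perl = TRUE))
    if (length(m)) return(m[[1]])
  }
  NULL
}

nexus_command <- function(block, name) {
  m <- regmatches(block, regexpr(
    paste0("(?is)\\b", name, "\\b[^;]*;"), block, perl = TRUE))
  if (length(m)) m[[1]] else NULL
}

nexus_number <- function(block, key) {
  m <- regmatches(block, regexpr(
    paste0("(?i)", key, "\\s*=\\s*[0-9]+"), block, perl = TRUE))
  if (!length(m)) return(NA_integer_)
  as.integer(sub(".*=\\s*", "", m[[1]]))
}

nexus_option <- function(cmd, key, default) {
  if (is.null(cmd)) return(default)
  m <- regmatches(cmd, regexpr(
    paste0("(?i)", key, "\\s*=\\s*(\"[^\"]*\"|\\S+)"), cmd, perl = TRUE))
  if (!length(m)) return(default)
  val <- sub("(?i).*=\\s*", "", m[[1]], perl = TRUE)
  gsub(";$", "", val)
}

## Returns list(taxon=, states=integer vector of bitmasks; -1 == missing),
## or NULL for non-data lines.
parse_matrix_row <- function(row, missing_sym, gap_sym, allowed) {
  row <- trimws(row)
  if (row == "" || row == ";") return(NULL)
  if (startsWith(row, "'")) {
    close <- regexpr("'", substring(row, 2), fixed = TRUE)
    if (close < 0) stop("unterminated quoted taxon label in row: ", row)
    taxon <- substring(row, 2, close)
    rest <- substring(row, close + 2)
  } else {
    sp <- regexpr("\\s", row)
    if (sp < 0) return(NULL)
    taxon <- substring(row, 1, sp - 1)
    rest <- substring(row, sp + 1)
  }
  rest <- gsub("\\s", "", rest)
  chars <- strsplit(rest, "")[[1]]
  states <- integer(0)
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == missing_sym || ch == gap_sym) {
      states <- c(states, -1L)
      i <- i + 1L
    } else if (ch == "(" || ch == "{") {
      closer <- if (ch == "(") ")" else "}"
      j <- i + 1L
      set <- integer(0)
      while (j <= length(chars) && chars[j] != closer) {
        set <- c(set, symbol_state(chars[j], allowed, row))
        j <- j + 1L
      }
      if (j > length(chars)) stop("unterminated polymorphism in row: ", row)
      if (!length(set)) stop("empty polymorphism in row: ", row)
      states <- c(states, states_to_mask(set))
      i <- j + 1L
    } else {
      states <- c(states, states_to_mask(symbol_state(ch, allowed, row)))
      i <- i + 1L
    }
  }
  list(taxon = normalize_labels(taxon), states = states)
}

symbol_state <- function(ch, allowed, row) {
  if (!grepl("[0-9]", ch)) {
    stop(sprintf("symbol '%s' outside declared state symbols in row: %s", ch, row))
  }
  if (!is.null(allowed) && !(ch %in% allowed)) {
    stop(sprintf("symbol '%s' outside declared SYMBOLS in row: %s", ch, row))
  }
  as.integer(ch)
}

## ---- writing ---------------------------------------------------------------

#' Write a character matrix as NEXUS (standard datatype)
#'
#' @param x a \code{char_matrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_nexus_matrix <- function(x, path) {
  symbols <- paste(0:(max(x$n_states) - 1L), collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", x$n_taxa, x$n_char), con)
  writeLines(sprintf(
    "  FORMAT DATATYPE=STANDARD MISSING=? GAP=- SYMBOLS=\"%s\";", symbols), con)
  writeLines("  MATRIX", con)
  width <- max(nchar(x$taxa)) + 2L
  for (t in seq_len(x$n_taxa)) {
    cells <- vapply(seq_len(x$n_char), function(j) {
      mask <- x$masks[t, j]
      full <- bitwShiftL(1L, x$n_states[j]) - 1L
      if (mask == full && x$n_states[j] > 1L) return("?")
      st <- mask_to_states(mask)
      if (length(st) == 1L) as.character(st) else
        paste0("(", paste(st, collapse = ""), ")")
    }, "")
    writeLines(sprintf("  %-*s%s", width, x$taxa[t],
                       paste(cells, collapse = "")), con)
  }
  writeLines("  ;", con)
  writeLines("END;", con)
  invisible(path)
}

## ---- tip ages --------------------------------------------------------------

#' Read a tip-age table
#'
#' Reads a CSV with columns \code{taxon}, \code{min_ma}, \code{max_ma} giving
#' each taxon's stratigraphic age interval in Ma (extant taxa as 0,0) and
#' validates it against a character matrix: every matrix taxon must have
#' exactly one non-negative interval with \code{min_ma <= max_ma}.
#'
#' @param path CSV path.
#' @param matrix optional \code{char_matrix} to validate against.
#' @return data.frame with columns \code{taxon}, \code{min_ma}, \code{max_ma},
#'   class \code{tip_ages}.
#' @export
parse_tip_ages <- function(path, matrix = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("taxon", "min_ma", "max_ma")
  if (!all(need %in% names(df))) {
    stop("tip-age CSV must have columns: ", paste(need, collapse = ", "))
  }
  tip_ages(df$taxon, df$min_ma, df$max_ma, matrix = matrix)
}

#' Construct a validated tip-age table
#'
#' @param taxon taxon labels.
#' @param min_ma,max_ma interval endpoints in Ma.
#' @param matrix optional \code{char_matrix}; if given, the table must cover
#'   its taxa exactly once each.
#' @return a \code{tip_ages} data.frame.
#' @export
tip_ages <- function(taxon, min_ma, max_ma, matrix = NULL) {
  df <- data.frame(taxon = normalize_labels(taxon),
                   min_ma = as.numeric(min_ma),
                   max_ma = as.numeric(max_ma),
                   stringsAsFactors = FALSE)
  bad <- df$taxon[df$min_ma > df$max_ma]
  if (length(bad)) stop("min_ma > max_ma for: ", paste(bad, collapse = ", "))
  bad <- df$taxon[df$min_ma < 0 | df$max_ma < 0]
  if (length(bad)) stop("negative ages for: ", paste(bad, collapse = ", "))
  if (anyDuplicated(df$taxon)) {
    stop("duplicate rows for: ",
         paste(unique(df$taxon[duplicated(df$taxon)]), collapse = ", "))
  }
  if (!is.null(matrix)) {
    missing <- setdiff(matrix$taxa, df$taxon)
    if (length(missing)) {
      stop("tip-age table lacks matrix taxa: ", paste(missing, collapse = ", "))
    }
    df <- df[match(matrix$taxa, df$taxon), , drop = FALSE]
    rownames(df) <- NULL
  }
  class(df) <- c("tip_ages", "data.frame")
  df
}

#' Write a tip-age table to CSV
#' @param x a \code{tip_ages} data.frame.
#' @param path output path.
#' @export
write_tip_ages <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- small helpers shared across modules -----------------------------------

## subset a char_matrix to (and reorder as) the given taxa
subset_matrix <- function(x, taxa) {
  taxa <- normalize_labels(taxa)
  missing <- setdiff(taxa, x$taxa)
  if (length(missing)) stop("taxa not in matrix: ", paste(missing, collapse = ", "))
  char_matrix(taxa, x$masks[taxa, , drop = FALSE])
}

## resample characters (bootstrap) -> new char_matrix with same taxa
resample_characters <- function(x, idx) {
  char_matrix(x$taxa, x$masks[, idx, drop = FALSE])
}
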