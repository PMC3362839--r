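## File formats: TSV matrices and peak tables, NEXUS standard/binary
## characters, Newick trees with support labels, JSON reports.

#' Write a binary character matrix
#'
#' TSV dialect: samples as rows, first column `sample`, one column per
#' locus; the species map goes to a sidecar `<path>.species.tsv`
#' (columns `sample`, `species`; replicate rows carry species `NA`).
#' NEXUS dialect: `datatype=standard`, `symbols="01"`, `missing=?`, with a
#' `SETS` block of one `TAXSET` per species.
#'
#' @param x an [aflp_binary]
#' @param path output file
#' @param dialect `"tsv"` or `"nexus"`
#' @param interleave write the NEXUS matrix interleaved (60-column blocks)
#' @return `path`, invisibly
#' @export
write_binary_matrix <- function(x, path, dialect = c("tsv", "nexus"),
                                interleave = FALSE) {
  dialect <- match.arg(dialect)
  calls <- x$calls
  if (dialect == "tsv") {
    df <- data.frame(sample = rownames(calls), calls, check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    sp <- data.frame(sample = rownames(calls),
                     species = ifelse(rownames(calls) %in% names(x$species),
                                      x$species[rownames(calls)], NA),
                     replicate = rownames(calls) %in% x$replicates)
    write.table(sp, paste0(path, ".species.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    n <- nrow(calls); L <- ncol(calls)
    writeLines("#NEXUS", con)
    writeLines("BEGIN DATA;", con)
    writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n, L), con)
    writeLines(sprintf(
      "  FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?%s;",
      if (interleave) " INTERLEAVE" else ""), con)
    writeLines("  MATRIX", con)
    rows <- apply(calls, 1, paste, collapse = "")
    ids <- format(rownames(calls))
    if (interleave) {
      for (s in seq(1, L, by = 60)) {
        chunk <- substr(rows, s, min(s + 59, L))
        writeLines(paste("   ", ids, chunk), con)
        writeLines("", con)
      }
    } else {
      writeLines(paste("   ", ids, rows), con)
    }
    writeLines("  ;", con)
    writeLines("END;", con)
    if (length(x$species) > 0) {
      writeLines("BEGIN SETS;", con)
      for (sp in unique(x$species)) {
        members <- names(x$species)[x$species == sp]
        writeLines(sprintf("  TAXSET %s = %s;", sp,
                           paste(members, collapse = " ")), con)
      }
      writeLines("END;", con)
    }
  }
  invisible(path)
}

#' Read a binary character matrix
#'
#' Accepts the TSV and NEXUS dialects produced by [write_binary_matrix()]
#' (sequential or interleaved NEXUS). Cells other than 0/1 produce a parse
#' error naming the offending sample and locus.
#'
#' @param path input file
#' @param dialect `"tsv"` or `"nexus"`; default guesses from the first line
#' @param species optional named character vector overriding the species
#'   map; for TSV the sidecar `<path>.species.tsv` is read if present
#' @return an [aflp_binary]
#' @export
read_binary_matrix <- function(path, dialect = NULL, species = NULL) {
  first <- readLines(path, n = 1)
  if (is.null(dialect))
    dialect <- if (grepl("^#NEXUS", first, ignore.case = TRUE)) "nexus"
               else "tsv"
  if (dialect == "tsv") {
    df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                     colClasses = "character")
    ids <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    bad <- which(!(m %in% c("0", "1")), arr.ind = FALSE)
    if (length(bad) > 0) {
      rc <- arrayInd(bad[1], dim(m))
      stop("non-binary cell '", m[bad[1]], "' at sample ", ids[rc[1]],
           ", locus ", colnames(m)[rc[2]])
    }
    storage.mode(m) <- "integer"
    rownames(m) <- ids
    replicates <- character()
    side <- paste0(path, ".species.tsv")
    if (is.null(species) && file.exists(side)) {
      sp <- read.table(side, header = TRUE, sep = "\t",
                       colClasses = c("character", "character", "logical"))
      replicates <- sp$sample[sp$replicate]
      keep <- !sp$replicate & !is.na(sp$species)
      species <- setNames(sp$species[keep], sp$sample[keep])
    }
    if (is.null(species)) species <- setNames(ids, ids)
    return(aflp_binary(m, species, replicates))
  }
  parse_nexus_binary(path, species)
}

## Minimal NEXUS parser for datatype=standard binary matrices, sequential or
## interleaved, with an optional SETS block of TAXSETs for the species map.
parse_nexus_binary <- function(path, species = NULL) {
  lines <- readLines(path)
  txt <- paste(lines, collapse = "\n")
  mstart <- regexpr("MATRIX", txt, ignore.case = TRUE)
  if (mstart < 0) stop("no MATRIX block found in NEXUS file")
  rest <- substr(txt, mstart + 6, nchar(txt))
  mend <- regexpr(";", rest, fixed = TRUE)
  body <- substr(rest, 1, mend - 1)
  rows <- strsplit(body, "\n")[[1]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows)]
  acc <- list()
  order_seen <- character()
  for (r in rows) {
    parts <- strsplit(r, "[ \t]+")[[1]]
    id <- parts[1]
    dat <- paste(parts[-1], collapse = "")
    if (is.null(acc[[id]])) {
      acc[[id]] <- dat
      order_seen <- c(order_seen, id)
    } else {
      acc[[id]] <- paste0(acc[[id]], dat)   # interleaved continuation
    }
  }
  chars <- lapply(acc, function(s) strsplit(s, "")[[1]])
  L <- unique(lengths(chars))
  if (length(L) != 1)
    stop("ragged NEXUS matrix: rows of differing lengths")
  m <- do.call(rbind, chars)
  rownames(m) <- order_seen
  bad <- which(!(m %in% c("0", "1")))
  if (length(bad) > 0) {
    rc <- arrayInd(bad[1], dim(m))
    stop("non-binary cell '", m[bad[1]], "' at sample ",
         order_seen[rc[1]], ", character ", rc[2])
  }
  storage.mode(m) <- "integer"
  colnames(m) <- sprintf("L%04d", seq_len(ncol(m)))
  if (is.null(species)) {
    sets <- regmatches(txt,
                       gregexpr("TAXSET[ \t]+([^=]+)=[^;]+;", txt))[[1]]
    if (length(sets) > 0) {
      species <- character()
      for (s in sets) {
        s <- sub(";$", "", sub("TAXSET[ \t]+", "", s))
        kv <- strsplit(s, "=")[[1]]
        members <- strsplit(trimws(kv[2]), "[ \t]+")[[1]]
        species <- c(species, setNames(rep(trimws(kv[1]), length(members)),
                                       members))
      }
    } else {
      species <- setNames(order_seen, order_seen)
    }
  }
  replicates <- setdiff(order_seen, names(species))
  aflp_binary(m, species, replicates)
}

#' Write a peak-height table as TSV
#'
#' Heights go to `path` (rows = profiles, columns = bin labels); the
#' replicate pairing map goes to `<path>.pairs.tsv`.
#'
#' @param peaks an [aflp_peaks]
#' @param path output file
#' @export
write_peak_table <- function(peaks, path) {
  df <- data.frame(sample = rownames(peaks$heights), peaks$heights,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(peaks$replicate_pairs, paste0(path, ".pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a peak-height table written by [write_peak_table()]
#'
#' @param path input TSV
#' @param species optional named character vector sample -> species
#' @return an [aflp_peaks]
#' @export
read_peak_table <- function(path, species = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  bins <- as.numeric(sub("^bin", "", colnames(m)))
  pair_path <- paste0(path, ".pairs.tsv")
  pairs <- if (file.exists(pair_path)) {
    read.table(pair_path, header = TRUE, sep = "\t",
               colClasses = "character")
  } else {
    data.frame(sample = character(), replicate = character())
  }
  aflp_peaks(m, bins, pairs, species = species)
}

#' Write a tree as Newick, optionally masking weak support
#'
#' Support values live in `tree$node.label`. With
#' `suppress_below = 50` the rendered Newick omits labels of 50 or below,
#' mirroring the common figure convention of showing only bootstrap values
#' above 50; full values should always be kept in the support-table TSV.
#'
#' @param tree an [ape::phylo]
#' @param path output file
#' @param with_support keep node labels in the output
#' @param suppress_below numeric; node labels at or below this value are
#'   blanked in the rendered file (NULL keeps everything)
#' @export
write_tree <- function(tree, path, with_support = TRUE,
                       suppress_below = NULL) {
  phy <- tree
  if (!with_support) phy$node.label <- NULL
  if (with_support && !is.null(suppress_below) &&
      !is.null(phy$node.label)) {
    v <- suppressWarnings(as.numeric(phy$node.label))
    phy$node.label[!is.na(v) & v <= suppress_below] <- ""
  }
  ape::write.tree(phy, file = path, digits = 14)
  invisible(path)
}

#' Write a support table as TSV
#'
#' @param st a [support_table()]
#' @param path output file
#' @export
write_support_table <- function(st, path) {
  df <- as.data.frame(st)
  df$n_pseudoreplicates <- attr(st, "n_pseudoreplicates")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
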