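#' Multiple sequence alignments
#'
#' Alignments are stored as a character matrix (taxa x sites, upper case) over
#' the DNA alphabet plus IUPAC ambiguity codes, the gap `-` and the missing
#' symbol `?`. For likelihood purposes `-`, `?` and `N` are treated as fully
#' missing; other ambiguity codes are treated as partial information (the
#' conditional likelihood vector has ones for every compatible state).
#'
#' @param mat character matrix of single upper-case symbols with taxon names
#'   as rownames.
#' @return an object of class `dna_alignment`: a list with `seq` (the matrix),
#'   `taxa` and `n_site`.
#' @export
dna_alignment <- function(mat) {
  if (is.null(rownames(mat))) stop2("alignment matrix needs taxon rownames")
  if (anyDuplicated(rownames(mat)))
    stop2("duplicate taxon names: ",
          paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  mat <- toupper(mat)
  bad <- which(!(mat %in% names(iupac_partials())))
  if (length(bad)) {
    site <- ((bad[1L] - 1L) %/% nrow(mat)) + 1L
    taxon <- rownames(mat)[((bad[1L] - 1L) %% nrow(mat)) + 1L]
    stop2("unknown symbol '", mat[bad[1L]], "' at site ", site,
          " of taxon '", taxon, "'")
  }
  structure(list(seq = mat, taxa = rownames(mat), n_site = ncol(mat)),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("dna_alignment:", length(x$taxa), "taxa x", x$n_site, "sites;",
      sprintf("%.2f%%", 100 * missing_fraction(x)), "missing\n")
  invisible(x)
}

# IUPAC code -> 0/1 likelihood vector over (A, C, G, T)
iupac_partials <- function() {
  list(A = c(1,0,0,0), C = c(0,1,0,0), G = c(0,0,1,0), T = c(0,0,0,1),
       U = c(0,0,0,1),
       R = c(1,0,1,0), Y = c(0,1,0,1), S = c(0,1,1,0), W = c(1,0,0,1),
       K = c(0,0,1,1), M = c(1,1,0,0),
       B = c(0,1,1,1), D = c(1,0,1,1), H = c(1,1,0,1), V = c(1,1,1,0),
       N = c(1,1,1,1), `-` = c(1,1,1,1), `?` = c(1,1,1,1))
}

#' Fraction of missing data in an alignment
#'
#' Counts cells that carry no state information: `-`, `?` and `N`.
#'
#' @param align a [dna_alignment()].
#' @return fraction in `[0, 1]`.
#' @export
missing_fraction <- function(align) {
  mean(align$seq %in% c("-", "?", "N"))
}

#' Read an alignment from FASTA or NEXUS
#'
#' All sequences must have equal length (the data are an alignment, not raw
#' reads); a ragged input is rejected naming the offending taxon.
#'
#' @param path file path.
#' @param format `"fasta"` or `"nexus"`.
#' @return a [dna_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "nexus")) {
  format <- match.arg(format)
  if (format == "fasta") {
    d <- ape::read.FASTA(path)
    len <- lengths(d)
    if (length(unique(len)) > 1L) {
      bad <- names(d)[which(len != len[1L])[1L]]
      stop2("sequences have unequal lengths: taxon '", bad, "' has ",
            len[[bad]], " sites, expected ", len[1L])
    }
    mat <- toupper(as.character(as.matrix(d)))
  } else {
    d <- ape::read.nexus.data(path)
    len <- lengths(d)
    if (length(unique(len)) > 1L) {
      bad <- names(d)[which(len != len[1L])[1L]]
      stop2("sequences have unequal lengths: taxon '", bad, "'")
    }
    mat <- toupper(do.call(rbind, d))
    rownames(mat) <- names(d)
  }
  dna_alignment(mat)
}

#' Write an alignment to FASTA or NEXUS
#'
#' NEXUS output can carry the partition scheme as `charset` lines in a sets
#' block so the file round-trips with external phylogenetics tools.
#'
#' @param align a [dna_alignment()].
#' @param path output file path.
#' @param format `"fasta"` or `"nexus"`.
#' @param scheme optional [partition_scheme()] written as a NEXUS sets block.
#' @export
write_alignment <- function(align, path, format = c("fasta", "nexus"),
                            scheme = NULL) {
  format <- match.arg(format)
  if (format == "fasta") {
    con <- file(path, "w"); on.exit(close(con))
    for (i in seq_along(align$taxa)) {
      writeLines(paste0(">", align$taxa[i]), con)
      writeLines(paste(align$seq[i, ], collapse = ""), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    nt <- length(align$taxa); ns <- align$n_site
    writeLines(c("#NEXUS", "", "BEGIN DATA;",
                 paste0("  DIMENSIONS NTAX=", nt, " NCHAR=", ns, ";"),
                 "  FORMAT DATATYPE=DNA MISSING=? GAP=-;", "  MATRIX"), con)
    pad <- max(nchar(align$taxa)) + 2L
    for (i in seq_len(nt))
      writeLines(paste0("    ", formatC(align$taxa[i], width = -pad),
                        paste(align$seq[i, ], collapse = "")), con)
    writeLines(c("  ;", "END;"), con)
    if (!is.null(scheme)) {
      writeLines(c("", "BEGIN SETS;"), con)
      for (g in scheme$groups) {
        writeLines(paste0("  CHARSET ", g$name, " = ",
                          paste(compress_ranges(g$sites), collapse = " "), ";"),
                   con)
      }
      writeLines("END;", con)
    }
  }
  invisible(path)
}

# express a sorted site index vector as NEXUS-style ranges, with /3 steps
compress_ranges <- function(sites) {
  sites <- sort(sites)
  out <- character(0)
  i <- 1L
  while (i <= length(sites)) {
    # try an arithmetic run with step 3 first (codon positions), then step 1
    for (step in c(3L, 1L)) {
      j <- i
      while (j < length(sites) && sites[j + 1L] == sites[j] + step) j <- j + 1L
      if (j - i >= 2L || (step == 1L)) break
    }
    if (j == i) out <- c(out, as.character(sites[i]))
    else if (step == 1L) out <- c(out, paste0(sites[i], "-", sites[j]))
    else out <- c(out, paste0(sites[i], "-", sites[j], "\\3"))
    i <- j + 1L
  }
  out
}
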