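#' RNA helix duplex
#'
#' A contiguous double helix given as its two strands, both written 5'->3'.
#' Position `i` of `strand5` pairs with position `n + 1 - i` of `strand3`
#' (antiparallel registration). Watson-Crick and G.U wobble pairs are
#' accepted; any other apposition is rejected, because the peripheral-helix
#' variants this package scores are contiguous helices without internal loops
#' or bulges. DNA-style `T` is normalized to `U` with a warning.
#'
#' @param strand5 RNA sequence (A/C/G/U) of one strand, 5'->3'
#' @param strand3 RNA sequence of the pairing partner, 5'->3'
#' @param closing_loop optional hairpin loop length (nt, >= 3) if the helix is
#'   capped by a loop
#' @param id construct label
#' @return an object of class `helix_duplex` with a derived `pairs` matrix
#' @export
helix_duplex <- function(strand5, strand3, closing_loop = NULL,
                         id = "helix") {
  norm <- function(s, which) {
    s <- toupper(gsub("\\s", "", s))
    if (grepl("T", s)) {
      warning(sprintf("strand %s of '%s': T normalized to U", which, id),
              call. = FALSE)
      s <- gsub("T", "U", s)
    }
    if (grepl("[^ACGU]", s)) {
      stop(sprintf("non-RNA characters in strand %s of '%s'", which, id),
           call. = FALSE)
    }
    s
  }
  strand5 <- norm(strand5, "5'")
  strand3 <- norm(strand3, "3'")
  if (nchar(strand5) != nchar(strand3)) {
    stop(sprintf("'%s': strand lengths differ (%d vs %d)", id,
                 nchar(strand5), nchar(strand3)), call. = FALSE)
  }
  if (nchar(strand5) < 1) stop("empty duplex", call. = FALSE)
  s5 <- strsplit(strand5, "")[[1]]
  s3 <- strsplit(strand3, "")[[1]]
  n <- length(s5)
  partner <- rev(s3)  # partner[i] pairs s5[i]
  ok <- paste0(s5, partner) %in%
    c("AU", "UA", "CG", "GC", "GU", "UG")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("'%s': position %d is %s-%s, not a Watson-Crick or G.U pair",
                 id, bad, s5[bad], partner[bad]), call. = FALSE)
  }
  if (!is.null(closing_loop)) {
    closing_loop <- as.integer(closing_loop)
    if (closing_loop < 3) {
      stop("hairpin loops shorter than 3 nt are sterically forbidden",
           call. = FALSE)
    }
  }
  structure(list(id = id, strand5 = strand5, strand3 = strand3,
                 pairs = cbind(s5, partner), n_bp = n,
                 closing_loop = closing_loop),
            class = "helix_duplex")
}

#' @export
print.helix_duplex <- function(x, ...) {
  cat(sprintf("<helix_duplex> %s: %d bp%s\n  5'-%s-3'\n  3'-%s-5'\n",
              x$id, x$n_bp,
              if (is.null(x$closing_loop)) ""
              else sprintf(" + %d-nt hairpin loop", x$closing_loop),
              x$strand5, paste(rev(strsplit(x$strand3, "")[[1]]), collapse = "")))
  invisible(x)
}

#' Load a nearest-neighbor parameter table
#'
#' Reads a versioned CSV of Turner-style free-energy parameters at 37 degrees
#' C: stacking terms for every ordered dinucleotide step over Watson-Crick
#' and G.U pairs, duplex initiation, the terminal AU/GU penalty, and hairpin
#' loop penalties by length. The table is checked for strand-flip symmetry
#' (a step and its rotated equivalent must have equal energy) on load. The
#' bundled default is the Turner 2004 set as distributed with ViennaRNA.
#'
#' @param path CSV file; default is the bundled table
#' @return an object of class `nn_param_table`
#' @export
nn_param_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_turner2004.csv", package = "ribopinch")
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("record_type", "key", "dG37_kcal") %in% names(tab)))
  st <- tab[tab$record_type == "stack", ]
  stacks <- stats::setNames(st$dG37_kcal, st$key)
  # strand-flip symmetry: 5'XY/3'WZ rotated is 5'ZW/3'YX
  for (k in names(stacks)) {
    flip <- paste0(substr(k, 5, 5), substr(k, 4, 4), "/",
                   substr(k, 2, 2), substr(k, 1, 1))
    if (!flip %in% names(stacks) ||
        abs(stacks[[k]] - stacks[[flip]]) > 1e-9) {
      stop("parameter table violates strand-flip symmetry at step ", k,
           call. = FALSE)
    }
  }
  hp <- tab[tab$record_type == "hairpin_loop", ]
  structure(
    list(stacks = stacks,
         init = tab$dG37_kcal[tab$record_type == "init"][1],
         terminal_au = tab$dG37_kcal[tab$record_type == "terminal_au"][1],
         hairpin_loop = stats::setNames(hp$dG37_kcal, hp$key),
         provenance = tab$key[tab$record_type == "provenance"][1]),
    class = "nn_param_table"
  )
}

# Step key for positions i, i+1 of a duplex: 5'-X1 X2-3' over 3'-Y1 Y2-5'.
step_key <- function(h, i) {
  paste0(h$pairs[i, 1], h$pairs[i + 1, 1], "/",
         h$pairs[i, 2], h$pairs[i + 1, 2])
}

#' Nearest-neighbor folding free energy of a helix at 37 degrees C
#'
#' Additive model: duplex initiation + the stacking term of each of the
#' `n - 1` dinucleotide steps + a terminal penalty for each helix end closed
#' by an A-U or G-U pair + (optionally) a hairpin-loop penalty when the helix
#' is capped by a loop. More negative values mean a more stable helix. This
#' is the package's stability proxy for a peripheral helical domain; callers
#' holding externally computed minimum-free-energy values for whole constructs
#' can use those directly in the coupling regressions instead.
#'
#' @param h a [helix_duplex()]
#' @param params an [nn_param_table()]
#' @param include_loop add the hairpin penalty when `h` carries a
#'   `closing_loop`; default is to include it whenever present
#' @return free energy in kcal/mol
#' @export
helix_dG37 <- function(h, params = nn_param_table(),
                       include_loop = !is.null(h$closing_loop)) {
  stopifnot(inherits(h, "helix_duplex"), inherits(params, "nn_param_table"))
  dG <- params$init
  if (h$n_bp >= 2) {
    for (i in seq_len(h$n_bp - 1)) {
      k <- step_key(h, i)
      if (!k %in% names(params$stacks)) {
        stop("no stacking parameter for step ", k, call. = FALSE)
      }
      dG <- dG + params$stacks[[k]]
    }
  }
  ends <- c(paste0(h$pairs[1, 1], h$pairs[1, 2]),
            paste0(h$pairs[h$n_bp, 1], h$pairs[h$n_bp, 2]))
  weak <- c("AU", "UA", "GU", "UG")
  dG <- dG + params$terminal_au * sum(ends %in% weak)
  if (include_loop) {
    if (is.null(h$closing_loop)) {
      stop("`include_loop = TRUE` but the duplex has no closing loop",
           call. = FALSE)
    }
    key <- as.character(min(h$closing_loop, 30L))
    dG <- dG + params$hairpin_loop[[key]]
  }
  unname(dG)
}

#' Information content of a helix
#'
#' Each base pair contributes 2 bits (one of four nucleotides on one strand,
#' the partner then determined), so a 5-bp extension adds 10 bits.
#'
#' @param n_bp number of base pairs (>= 0)
#' @return information content in bits (`2 * n_bp`)
#' @export
info_bits <- function(n_bp) {
  if (any(!is.finite(n_bp)) || any(n_bp < 0)) {
    stop("`n_bp` must be a non-negative count", call. = FALSE)
  }
  2 * n_bp
}

#' Parse helix constructs from a FASTA file
#'
#' Two dialects, chosen per record from the header:
#' * paired records: two consecutive records form one construct, first the
#'   5' strand then the 3' strand (both 5'->3'); the construct id is the
#'   first header's first word.
#' * hairpin records: a single record whose header carries `loop=<n>`; the
#'   sequence is `strand5 + loop + strand3` and is split symmetrically.
#'
#' `T` is normalized to `U` with a warning; non-pairing appositions are
#' rejected by [helix_duplex()].
#'
#' @param path FASTA file
#' @return a list of [helix_duplex()] objects
#' @export
parse_construct_fasta <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no records in ", path, call. = FALSE)
  headers <- names(seqs)
  out <- list()
  i <- 1L
  while (i <= length(seqs)) {
    hd <- headers[i]
    id <- strsplit(trimws(hd), "\\s+")[[1]][1]
    loop_m <- regmatches(hd, regexpr("loop=\\d+", hd))
    if (length(loop_m) == 1) {
      loop <- as.integer(sub("loop=", "", loop_m))
      s <- as.character(seqs[[i]])
      stem <- nchar(s) - loop
      if (stem < 2 || stem %% 2 != 0) {
        stop(sprintf("record '%s': sequence length %d incompatible with loop=%d",
                     id, nchar(s), loop), call. = FALSE)
      }
      half <- stem / 2
      out[[length(out) + 1L]] <- helix_duplex(
        substr(s, 1, half), substr(s, half + loop + 1, nchar(s)),
        closing_loop = loop, id = id)
      i <- i + 1L
    } else {
      if (i + 1L > length(seqs)) {
        stop(sprintf("record '%s' has no pairing partner record", id),
             call. = FALSE)
      }
      out[[length(out) + 1L]] <- helix_duplex(
        as.character(seqs[[i]]), as.character(seqs[[i + 1L]]), id = id)
      i <- i + 2L
    }
  }
  out
}
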