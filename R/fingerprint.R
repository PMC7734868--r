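# Fragment fingerprints: hashed sets of linear atom-bond paths, compared
# with the Tanimoto measure. Path enumeration runs on a molecular graph
# derived from OpenBabel's MOL2 output (which carries explicit aromatic
# bond typing); hashing and set comparison are implemented here.

MOL2_BOND_SYMBOL <- c(`1` = "-", `2` = "=", `3` = "#", ar = ":", am = "-")

# Parse MOL2 text (possibly several molecules) into molecular graphs:
# list(elements, aromatic, bonds = data.frame(a, b, sym)).
parse_mol2 <- function(text) {
  blocks <- strsplit(text, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  lapply(blocks, function(blk) {
    lines <- strsplit(blk, "\n", fixed = TRUE)[[1]]
    a0 <- which(lines == "@<TRIPOS>ATOM")
    b0 <- which(lines == "@<TRIPOS>BOND")
    stopifnot(length(a0) == 1, length(b0) == 1)
    ends <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
    atom_lines <- lines[seq(a0 + 1L, min(ends[ends > a0]) - 1L)]
    atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
    bond_to <- min(ends[ends > b0]) - 1L
    bond_lines <- if (bond_to > b0) lines[seq(b0 + 1L, bond_to)] else character()
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    atoms <- do.call(rbind, strsplit(trimws(atom_lines), "[ \t]+"))
    elements <- sub("\\..*$", "", atoms[, 6])
    n <- length(elements)
    aromatic <- logical(n)
    bonds <- data.frame(a = integer(), b = integer(), sym = character())
    if (length(bond_lines) > 0) {
      bm <- do.call(rbind, strsplit(trimws(bond_lines), "[ \t]+"))
      a <- as.integer(bm[, 2]); b <- as.integer(bm[, 3])
      type <- bm[, 4]
      sym <- unname(MOL2_BOND_SYMBOL[type])
      sym[is.na(sym)] <- "-"
      aromatic[c(a[type == "ar"], b[type == "ar"])] <- TRUE
      bonds <- data.frame(a = a, b = b, sym = sym)
    }
    list(elements = elements, aromatic = aromatic, bonds = bonds)
  })
}

mol_graphs <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0)
  src <- paste0(paste(smiles, paste0("m", seq_along(smiles))), "\n",
                collapse = "")
  text <- tryCatch(ChemmineOB::convertFormat("SMI", "MOL2", src),
                   error = function(e) "")
  graphs <- if (nzchar(text)) parse_mol2(text) else list()
  if (length(graphs) != length(smiles)) {
    stop("unparseable structure among inputs; fingerprints require ",
         "standardized, parseable SMILES", call. = FALSE)
  }
  graphs
}

# 31-bit polynomial rolling hash of a fragment string; exact in doubles.
hash_fragment <- function(s) {
  h <- 0
  for (c in utf8ToInt(s)) h <- (h * 131 + c) %% 2147483647
  h
}

# All linear paths of 0..depth bonds in a molecular graph, as canonical
# strings (lexicographic min of the two read directions).
enumerate_paths <- function(graph, depth) {
  n <- length(graph$elements)
  if (n == 0) return(character())
  label <- ifelse(graph$aromatic, tolower(graph$elements), graph$elements)
  adj <- vector("list", n)
  if (nrow(graph$bonds) > 0) {
    for (k in seq_len(nrow(graph$bonds))) {
      a <- graph$bonds$a[k]; b <- graph$bonds$b[k]; s <- graph$bonds$sym[k]
      adj[[a]] <- rbind(adj[[a]], data.frame(to = b, sym = s))
      adj[[b]] <- rbind(adj[[b]], data.frame(to = a, sym = s))
    }
  }
  out <- new.env(parent = emptyenv())
  walk <- function(atom, visited, str, nbonds) {
    rev_str <- path_reverse(str)
    key <- if (str <= rev_str) str else rev_str
    assign(key, TRUE, envir = out)
    if (nbonds == depth || is.null(adj[[atom]])) return(invisible())
    nb <- adj[[atom]]
    for (k in seq_len(nrow(nb))) {
      to <- nb$to[k]
      if (!visited[to]) {
        v <- visited; v[to] <- TRUE
        walk(to, v, paste0(str, nb$sym[k], label[to]), nbonds + 1L)
      }
    }
  }
  for (a in seq_len(n)) {
    visited <- logical(n); visited[a] <- TRUE
    walk(a, visited, label[a], 0L)
  }
  ls(out)
}

# Reverse a path string "C-c:n" -> "n:c-C" (tokens are atom labels and
# single-character bond symbols).
path_reverse <- function(s) {
  toks <- regmatches(s, gregexpr("[A-Z][a-z]?|[a-z][a-z]?|[-=#:]", s))[[1]]
  paste(rev(toks), collapse = "")
}

#' Construct a fragment fingerprint from raw bits
#'
#' Low-level constructor, mainly useful for tests and for set arithmetic on
#' precomputed fingerprints.
#'
#' @param bits numeric vector of non-negative fragment identifiers.
#' @param depth maximum path length (bonds) the bits were derived at.
#' @return An object of class `frag_fp`.
#' @export
frag_fp <- function(bits, depth) {
  stopifnot(is.numeric(bits), all(bits >= 0), depth >= 1)
  structure(list(bits = sort(unique(as.numeric(bits))),
                 depth = as.integer(depth)),
            class = "frag_fp")
}

#' @export
print.frag_fp <- function(x, ...) {
  cat("<frag_fp> ", length(x$bits), " bits, depth ", x$depth, "\n", sep = "")
  invisible(x)
}

#' Fragment fingerprint of a structure
#'
#' Enumerates all linear atom-bond paths of up to `depth` bonds (including
#' single atoms), with atoms typed by element and aromaticity, and hashes
#' each canonical path string to an integer identifier. Identical
#' standardized structures yield identical bit sets at equal depth.
#'
#' @param smiles one standardized, parseable SMILES string.
#' @param depth maximum path length in bonds (>= 1); default 7.
#' @return A `frag_fp` object.
#' @seealso [tanimoto()], [fragment_fingerprints()]
#' @export
fragment_fingerprint <- function(smiles, depth = 7L) {
  fragment_fingerprints(smiles, depth = depth)[[1]]
}

#' Fragment fingerprints for a vector of structures
#'
#' @inheritParams fragment_fingerprint
#' @param smiles character vector of standardized SMILES.
#' @return A list of `frag_fp` objects, named after `names(smiles)` if set.
#' @export
fragment_fingerprints <- function(smiles, depth = 7L) {
  stopifnot(depth >= 1)
  graphs <- mol_graphs(smiles)
  fps <- lapply(graphs, function(g) {
    paths <- enumerate_paths(g, as.integer(depth))
    frag_fp(vapply(paths, hash_fragment, numeric(1), USE.NAMES = FALSE),
            depth = depth)
  })
  names(fps) <- names(smiles)
  fps
}

#' Tanimoto similarity of two fragment fingerprints
#'
#' `|A intersect B| / |A union B|` over the fingerprint bit sets. Two empty
#' fingerprints (the empty molecule) compare as 1 by convention.
#'
#' @param a,b `frag_fp` objects computed at the same depth.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "frag_fp"), inherits(b, "frag_fp"))
  if (a$depth != b$depth) {
    stop("fingerprints computed at different depths (", a$depth, " vs ",
         b$depth, ") are not comparable", call. = FALSE)
  }
  n_int <- length(intersect(a$bits, b$bits))
  n_uni <- length(a$bits) + length(b$bits) - n_int
  if (n_uni == 0) return(1)
  n_int / n_uni
}

#' All-pairs Tanimoto similarity between two fingerprint lists
#'
#' @param fps_a,fps_b lists of `frag_fp` objects at a common depth.
#' @return A `length(fps_a)` by `length(fps_b)` numeric matrix.
#' @export
tanimoto_matrix <- function(fps_a, fps_b) {
  stopifnot(length(fps_a) > 0, length(fps_b) > 0)
  depths <- unique(vapply(c(fps_a, fps_b), `[[`, integer(1), "depth"))
  if (length(depths) != 1) {
    stop("all fingerprints must share one depth setting", call. = FALSE)
  }
  all_bits <- unique(unlist(c(lapply(fps_a, `[[`, "bits"),
                              lapply(fps_b, `[[`, "bits"))))
  ind <- function(fps) {
    i <- rep(seq_along(fps), vapply(fps, function(f) length(f$bits), 0L))
    j <- match(unlist(lapply(fps, `[[`, "bits")), all_bits)
    Matrix::sparseMatrix(i = i, j = j, x = 1,
                         dims = c(length(fps), length(all_bits)))
  }
  ma <- ind(fps_a); mb <- ind(fps_b)
  inter <- as.matrix(Matrix::tcrossprod(ma, mb))
  na <- Matrix::rowSums(ma); nb <- Matrix::rowSums(mb)
  uni <- outer(na, nb, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  dimnames(sim) <- list(names(fps_a), names(fps_b))
  sim
}
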