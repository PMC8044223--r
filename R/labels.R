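#' Target records: the sequence a prediction refers to
#'
#' @param target_id Target identifier.
#' @param sequence Amino-acid sequence over the 20-letter alphabet plus X.
#' @return An object of class `target_record` with fields `target_id`,
#'   `sequence`, `L`.
#' @export
target_record <- function(target_id, sequence) {
  sequence <- toupper(gsub("\\s", "", as.character(sequence)[1]))
  if (nchar(sequence) == 0) stop("empty target sequence", call. = FALSE)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)) {
    stop("sequence contains letters outside the amino-acid alphabet",
         call. = FALSE)
  }
  structure(list(target_id = as.character(target_id)[1],
                 sequence = sequence, L = nchar(sequence)),
            class = "target_record")
}

#' Read a single-sequence FASTA file into a target record
#'
#' @param path FASTA file with one sequence; the first word of the header
#'   becomes the target id.
#' @return A [target_record()].
#' @export
read_target_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fa <- bio3d::read.fasta(path)
  seqs <- apply(fa$ali, 1, function(r) paste(r[r != "-"], collapse = ""))
  if (length(seqs) > 1) {
    message("FASTA has ", length(seqs), " sequences; using the first")
  }
  target_record(fa$id[1], seqs[1])
}

#' Write a target record as FASTA
#' @param target A [target_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_fasta <- function(target, path) {
  stopifnot(inherits(target, "target_record"))
  writeLines(c(paste0(">", target$target_id),
               substring(target$sequence,
                         seq(1, target$L, by = 60),
                         pmin(seq(1, target$L, by = 60) + 59, target$L))),
             path)
  invisible(path)
}

#' Structure chains: residue positions with representative coordinates
#'
#' A structure chain is the label-side view of a target: an ordered list of
#' residues, each carrying its 1-based position in the target sequence, its
#' amino-acid letter, and the 3D coordinate of its representative atom
#' (C-beta, or C-alpha for glycine), or `NA` coordinates when the residue is
#' unresolved.
#'
#' @param target_id Target identifier.
#' @param pos Integer vector of strictly increasing 1-based sequence
#'   positions.
#' @param aa Character vector of one-letter amino-acid codes.
#' @param xyz Numeric matrix `length(pos) x 3` of coordinates in Angstrom
#'   (`NA` rows for unresolved residues).
#' @return An object of class `structure_chain`.
#' @export
structure_chain <- function(target_id, pos, aa, xyz) {
  pos <- as.integer(pos)
  stopifnot(length(pos) == length(aa), nrow(xyz) == length(pos),
            ncol(xyz) == 3)
  if (any(diff(pos) <= 0)) {
    stop("sequence positions must be strictly increasing", call. = FALSE)
  }
  structure(list(target_id = as.character(target_id)[1],
                 residues = data.frame(pos = pos, aa = toupper(aa),
                                       x = xyz[, 1], y = xyz[, 2],
                                       z = xyz[, 3],
                                       stringsAsFactors = FALSE)),
            class = "structure_chain")
}

# Pick the representative-atom row for one residue's atom records:
# C-beta, or C-alpha for glycine; non-glycine residues missing C-beta fall
# back to C-alpha with a warning; NA if neither atom exists.
pick_representative <- function(elety, aa) {
  want <- if (aa == "G") "CA" else "CB"
  hit <- which(elety == want)
  if (length(hit)) return(hit[1])
  if (want == "CB") {
    hit <- which(elety == "CA")
    if (length(hit)) {
      warning("residue lacks CB; falling back to CA", call. = FALSE)
      return(hit[1])
    }
  }
  NA_integer_
}

#' Read structure chains from a PDB file
#'
#' Reads a (possibly multi-MODEL) PDB file and extracts one
#' [structure_chain()] per model for a single chain, using the residue
#' numbers as 1-based positions into the target sequence. Representative
#' coordinates follow the standard contact-definition rule: the C-beta atom,
#' or C-alpha for glycine; non-glycine residues without a C-beta fall back
#' to C-alpha (with a warning), and residues with neither atom are kept as
#' unresolved. In multi-chain files only the requested (or first) chain is
#' read; the others are noted in a message.
#'
#' @param path Path to a PDB file.
#' @param target_id Target identifier (default: file base name).
#' @param chain Chain identifier; default is the first chain in the file.
#' @return A list of [structure_chain()], one per MODEL (length 1 for
#'   X-ray-style single-model files).
#' @export
read_structure_models <- function(path, target_id = NULL, chain = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(target_id)) {
    target_id <- sub("\\.[^.]*$", "", basename(path))
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  prot <- which(at$type == "ATOM")
  if (!length(prot)) stop("no ATOM records in ", path, call. = FALSE)
  chains <- unique(at$chain[prot])
  if (is.null(chain)) chain <- chains[1]
  if (length(chains) > 1) {
    message("PDB ", basename(path), " has chains ",
            paste(chains, collapse = ", "), "; using chain ", chain)
  }
  rows <- prot[at$chain[prot] == chain]
  if (!length(rows)) stop("chain '", chain, "' not found in ", path,
                          call. = FALSE)
  resnos <- sort(unique(at$resno[rows]))
  aa <- character(length(resnos))
  atom_row <- integer(length(resnos))
  for (k in seq_along(resnos)) {
    rr <- rows[at$resno[rows] == resnos[k]]
    aa[k] <- bio3d::aa321(at$resid[rr[1]])
    pick <- pick_representative(at$elety[rr], aa[k])
    atom_row[k] <- if (is.na(pick)) NA_integer_ else rr[pick]
  }
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  lapply(seq_len(nrow(xyz)), function(m) {
    coords <- matrix(NA_real_, length(resnos), 3)
    ok <- !is.na(atom_row)
    cols <- cbind(3 * atom_row[ok] - 2, 3 * atom_row[ok] - 1,
                  3 * atom_row[ok])
    coords[ok, ] <- matrix(xyz[m, cols], ncol = 3)
    structure_chain(target_id, resnos, aa, coords)
  })
}

#' Reconcile a structure chain with the prediction sequence
#'
#' Residues whose amino-acid letter disagrees with the target sequence at
#' their position are removed from analysis (they cannot be attributed to
#' the predicted sequence); surviving residues keep their original
#' positions, so no renumbering occurs. Positions beyond the target length
#' are likewise dropped.
#'
#' @param chain A [structure_chain()].
#' @param target A [target_record()].
#' @return The edited [structure_chain()]; the dropped positions are
#'   attached as attribute `"dropped"`.
#' @export
reconcile <- function(chain, target) {
  stopifnot(inherits(chain, "structure_chain"),
            inherits(target, "target_record"))
  res <- chain$residues
  in_range <- res$pos >= 1 & res$pos <= target$L
  expected <- rep(NA_character_, nrow(res))
  expected[in_range] <- substring(target$sequence, res$pos[in_range],
                                  res$pos[in_range])
  keep <- in_range & res$aa == expected
  dropped <- res$pos[!keep]
  if (sum(keep) < 2) {
    stop("fewer than 2 residues agree with the target sequence; ",
         "empty label set", call. = FALSE)
  }
  out <- structure_chain(chain$target_id, res$pos[keep], res$aa[keep],
                         as.matrix(res[keep, c("x", "y", "z")]))
  attr(out, "dropped") <- dropped
  out
}

#' Pairwise representative-atom distance matrix
#'
#' Euclidean distances between the representative atoms of every residue
#' pair, as a full `L x L` matrix indexed by target-sequence position.
#' Pairs involving an unresolved residue (missing coordinates) or a position
#' absent from the chain are `NA`.
#'
#' @param chain A (reconciled) [structure_chain()].
#' @param L Target sequence length.
#' @return `L x L` symmetric numeric matrix in Angstrom with `NA` for
#'   unresolved pairs.
#' @export
distance_matrix <- function(chain, L) {
  stopifnot(inherits(chain, "structure_chain"))
  res <- chain$residues
  ok <- stats::complete.cases(res[, c("x", "y", "z")])
  D <- matrix(NA_real_, L, L)
  pos <- res$pos[ok]
  if (length(pos)) {
    D[pos, pos] <- as.matrix(stats::dist(res[ok, c("x", "y", "z")]))
  }
  D
}

#' Mean distance matrix over an ensemble of structure models
#'
#' Per-pair arithmetic mean of the distance matrices of several models of
#' the same target (e.g. the models of an NMR ensemble). A pair contributes
#' from every model in which it is resolved and is `NA` only if unresolved
#' in all models.
#'
#' @param models List of [structure_chain()], all reconciled against the
#'   same target.
#' @param L Target sequence length.
#' @return `L x L` mean distance matrix.
#' @export
mean_distance_matrix <- function(models, L) {
  if (!length(models)) stop("need at least one model", call. = FALSE)
  mats <- lapply(models, distance_matrix, L = L)
  total <- matrix(0, L, L)
  count <- matrix(0L, L, L)
  for (D in mats) {
    ok <- !is.na(D)
    total[ok] <- total[ok] + D[ok]
    count[ok] <- count[ok] + 1L
  }
  out <- total / count
  out[count == 0] <- NA_real_
  out
}

#' Derive true contacts from a distance matrix
#'
#' All resolved residue pairs separated by at least 6 positions along the
#' sequence and by at most `threshold` Angstrom in space are labeled
#' contacts, classed by [separation_class()]. The per-class counts are the
#' `n_true` values that set the ceiling of the normalized accuracy score.
#'
#' @param distances `L x L` distance matrix (possibly with `NA`).
#' @param threshold Contact distance threshold in Angstrom; default 8, with
#'   distances exactly at the threshold counting as contacts.
#' @param target_id Target identifier for the returned set.
#' @return A list with `contacts` (a `contact_set` data frame with a
#'   `distance` column) and `n_true` (named per-class counts).
#' @export
contacts_from_distances <- function(distances, threshold = 8,
                                    target_id = "unknown") {
  stopifnot(is.matrix(distances), nrow(distances) == ncol(distances))
  L <- nrow(distances)
  pr <- upper_pairs(L)
  d <- distances[pr]
  cls <- separation_class(pr[, 1], pr[, 2])
  keep <- !is.na(d) & cls != "excluded" & d <= threshold
  set <- contact_set(target_id, pr[keep, 1], pr[keep, 2],
                     class = cls[keep])
  set$distance <- d[keep]
  n_true <- vapply(contact_classes(),
                   function(cc) sum(set$class == cc), integer(1))
  list(contacts = set, n_true = n_true)
}

#' Build the ground-truth label set for a target
#'
#' Runs the full label pipeline: reconcile each structure model against the
#' target sequence, average the models' representative-atom distance
#' matrices, and derive the true contact set at the threshold.
#'
#' @param models A [structure_chain()] or list of them (NMR-style model
#'   ensembles).
#' @param target A [target_record()].
#' @param threshold Contact distance threshold in Angstrom (default 8).
#' @return An object of class `label_set` with fields `target_id`, `L`,
#'   `distances`, `contacts`, `n_true`, `dropped` (structure positions
#'   removed during reconciliation).
#' @export
build_labels <- function(models, target, threshold = 8) {
  stopifnot(inherits(target, "target_record"))
  if (inherits(models, "structure_chain")) models <- list(models)
  rec <- lapply(models, reconcile, target = target)
  D <- mean_distance_matrix(rec, target$L)
  lab <- contacts_from_distances(D, threshold, target$target_id)
  structure(list(target_id = target$target_id, L = target$L,
                 distances = D, contacts = lab$contacts,
                 n_true = lab$n_true,
                 dropped = sort(unique(unlist(lapply(rec, attr, "dropped"))))),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  cat(sprintf(
    "label_set for target '%s': L = %d; true contacts short/mid/long = %d/%d/%d\n",
    x$target_id, x$L, x$n_true["short"], x$n_true["mid"], x$n_true["long"]))
  invisible(x)
}

#' Export a label set as CSV
#'
#' One row per true contact: `i`, `j`, `distance`, `class`, `is_contact`.
#'
#' @param labels A [build_labels()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_label_csv <- function(labels, path) {
  stopifnot(inherits(labels, "label_set"))
  df <- data.frame(target_id = labels$target_id, i = labels$contacts$i,
                   j = labels$contacts$j,
                   distance = labels$contacts$distance,
                   class = labels$contacts$class, is_contact = TRUE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
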