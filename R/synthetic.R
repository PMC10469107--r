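# Synthetic multi-source drug corpus generator. Molecules are assembled from
# a curated aromatic-scaffold + substituent library (guaranteeing valid,
# multi-element, short SMILES), a toxicophore substituent is planted in a
# configurable fraction, true withdrawal labels follow a logistic model on
# fragment presence, and per-source observed labels flip with a configurable
# rate to create cross-source "no agreement" conflicts.

.SCAFFOLDS <- c(
  "c1cc(%s)ccc1%s",   # para-disubstituted benzene
  "c1cc(%s)cc(%s)c1", # meta-disubstituted benzene
  "c1cc(%s)cnc1%s",   # pyridine
  "c1cc(%s)oc1%s",    # furan
  "c1cc(%s)sc1%s",    # thiophene
  "c1cc(%s)ccc1C%s"   # benzyl-linked second substituent
)

.SUBSTITUENTS <- c(
  "C", "CC", "CCC", "C(C)C", "CCO", "CO", "O", "OC", "OCC", "N", "NC",
  "NCC", "Cl", "F", "Br", "C#N", "C(=O)O", "C(=O)N", "C(=O)C", "CC(=O)O",
  "S", "SC", "CCN", "C(F)(F)F", "CCCC", "COC", "CC(C)C", "CCOC", "OCCO",
  "NC(=O)C", "C(=O)OC", "CC#N", "CCS", "NCCO", "OCCC", "CNC"
)

# substituents ending in an atom that can take one more single bond
.EXTENDABLE <- c("C", "CC", "CCC", "CCCC", "C(C)C", "CCO", "CO", "O", "OC",
                 "OCC", "OCCC", "N", "NC", "NCC", "S", "SC", "CCN", "CNC")
.EXTENSIONS <- c("C", "CC", "CO", "CN")

# a base substituent, optionally chain-extended up to twice; extensions end
# in a single-bonded C/O/N so they can themselves be extended
.random_substituent <- function() {
  s <- sample(.SUBSTITUENTS, 1L)
  extendable <- s %in% .EXTENDABLE
  for (depth in 1:2) {
    if (!extendable || stats::runif(1) >= 0.5) break
    s <- paste0(s, sample(.EXTENSIONS, 1L))
  }
  s
}

#' Configuration of the synthetic corpus generator
#'
#' Defaults describe the benchmark world used throughout the test suite:
#' 500 molecules across 4 partially overlapping sources, a planted aromatic
#' nitro toxicophore in about half the molecules, true withdrawal odds
#' `logistic(alpha + beta * fragment)` with `alpha = -2`, `beta = 4` (overall
#' class balance near 1:1), and a 2% per-source label-flip rate creating
#' cross-source conflicts.
#'
#' @param n_molecules number of unique molecules (default 500).
#' @param n_sources number of sources (default 4; at least 2). Source 1 is
#'   the negative source: it annotates every molecule, emulating the role of
#'   the approved-drug reference database; the others annotate each molecule
#'   independently with probability `membership_prob`.
#' @param toxicophore substituent SMILES of the planted fragment (default
#'   the nitro group `[N+](=O)[O-]`, attached to an aromatic carbon).
#' @param beta log-odds increment for fragment presence (default 4).
#' @param alpha log-odds intercept (default -2).
#' @param frag_prob fraction of molecules carrying the fragment (default 0.5).
#' @param membership_prob per-source inclusion probability for non-negative
#'   sources (default 0.5).
#' @param flip_rate per-source probability that an observed label flips the
#'   true label (default 0.02).
#' @param seed integer seed.
#' @return list of class `withdrawr_synth_config`.
#' @export
synthetic_config <- function(n_molecules = 500L, n_sources = 4L,
                             toxicophore = "[N+](=O)[O-]", beta = 4,
                             alpha = -2, frag_prob = 0.5,
                             membership_prob = 0.5, flip_rate = 0.02,
                             seed = 1L) {
  stopifnot(n_molecules >= 1L, n_sources >= 2L,
            frag_prob >= 0, frag_prob <= 1,
            membership_prob >= 0, membership_prob <= 1,
            flip_rate >= 0, flip_rate <= 1)
  ok <- tryCatch({
    smiles_parse(paste0("C", toxicophore)); TRUE
  }, error = function(e) FALSE)
  if (!ok) {
    stop(sprintf("toxicophore fragment '%s' is not a valid substituent",
                 toxicophore))
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 n_sources = as.integer(n_sources),
                 toxicophore = toxicophore, beta = beta, alpha = alpha,
                 frag_prob = frag_prob, membership_prob = membership_prob,
                 flip_rate = flip_rate, seed = as.integer(seed)),
            class = "withdrawr_synth_config")
}

#' SMILES pattern matching the planted toxicophore
#'
#' The substituent library contains no copy of the default fragment, so
#' matching the bare fragment is equivalent to the generator's planting flag.
#'
#' @param config a [synthetic_config()].
#' @return pattern SMILES string for [smiles_has_substructure()].
#' @export
toxicophore_pattern <- function(config) config$toxicophore

#' Generate the molecule set of a synthetic corpus
#'
#' Assembles unique, valid, multi-element molecules from scaffold templates
#' and a substituent library; a configurable fraction carries the
#' toxicophore as one substituent. Emitted SMILES are canonical, so they
#' survive [standardize_database()] unchanged.
#'
#' @param config a [synthetic_config()]. Uses the R random number generator
#'   (seed it, or use [synthetic_corpus()] which seeds from the config).
#' @return data.frame: `key` (= canonical SMILES), `smiles`,
#'   `fragment_flag` (0/1).
#' @export
generate_molecules <- function(config) {
  n <- config$n_molecules
  # fix the fragment count up front so duplicate rejection (which hits the
  # smaller fragment-bearing space harder) cannot bias the realized fraction
  n_frag <- stats::rbinom(1L, n, config$frag_prob)
  seen <- new.env(parent = emptyenv())
  keys <- character(0); flags <- integer(0)
  tries <- 0L
  while (length(keys) < n) {
    tries <- tries + 1L
    if (tries > 200L * n) {
      stop("generate_molecules: could not assemble enough unique molecules")
    }
    has_frag <- sum(flags) < n_frag
    scaffold <- sample(.SCAFFOLDS, 1L)
    sub_a <- .random_substituent()
    sub_b <- .random_substituent()
    # the toxicophore replaces one of the two substituents at random
    if (has_frag) {
      if (stats::runif(1) < 0.5) sub_a <- config$toxicophore
      else sub_b <- config$toxicophore
    }
    smi <- sprintf(scaffold, sub_a, sub_b)
    key <- canonical_key(smi)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    keys <- c(keys, key)
    flags <- c(flags, as.integer(has_frag))
  }
  ord <- sample.int(n) # interleave fragment and plain molecules
  keys <- keys[ord]; flags <- flags[ord]
  data.frame(key = keys, smiles = keys, fragment_flag = flags,
             stringsAsFactors = FALSE)
}

#' Draw true withdrawal labels for generated molecules
#'
#' `P(withdrawn) = logistic(alpha + beta * fragment_flag)`.
#'
#' @param molecules data.frame from [generate_molecules()].
#' @param config a [synthetic_config()].
#' @return the data.frame with a `true_label` column added.
#' @export
assign_true_labels <- function(molecules, config) {
  p <- stats::plogis(config$alpha + config$beta * molecules$fragment_flag)
  molecules$true_label <- stats::rbinom(nrow(molecules), 1L, p)
  molecules
}

#' Distribute labeled molecules across synthetic sources
#'
#' Source 1 (the negative source) annotates every molecule; the remaining
#' sources annotate each molecule independently with `membership_prob`.
#' Every source's observed label flips the true label with probability
#' `flip_rate`, creating the cross-source conflicts of a no-agreement world.
#'
#' @param truth data.frame from [assign_true_labels()].
#' @param config a [synthetic_config()].
#' @return list with `databases` (named list of `withdrawr_database`),
#'   `truth` (the data.frame extended with per-source observed label columns
#'   `obs_<source>`, NA where not annotated) and `records` (a drug-record
#'   data.frame in the corpus-module input format).
#' @export
distribute_to_sources <- function(truth, config) {
  n <- nrow(truth)
  S <- config$n_sources
  src_names <- paste0("source", seq_len(S))
  member <- matrix(FALSE, n, S)
  member[, 1L] <- TRUE
  for (s in seq_len(S)[-1L]) {
    member[, s] <- stats::runif(n) < config$membership_prob
  }
  obs <- matrix(NA_integer_, n, S)
  for (s in seq_len(S)) {
    idx <- which(member[, s])
    flip <- stats::rbinom(length(idx), 1L, config$flip_rate)
    obs[idx, s] <- as.integer(xor(truth$true_label[idx] == 1L, flip == 1L))
  }
  colnames(obs) <- paste0("obs_", src_names)
  truth <- cbind(truth, as.data.frame(obs))

  databases <- stats::setNames(lapply(seq_len(S), function(s) {
    idx <- which(member[, s])
    .new_drug_database(src_names[s], data.frame(
      key = truth$key[idx], smiles = truth$smiles[idx],
      label = obs[idx, s],
      sources = src_names[s], stringsAsFactors = FALSE))
  }), src_names)

  records <- do.call(rbind, lapply(seq_len(S), function(s) {
    idx <- which(member[, s])
    # alternate raw status vocabularies across sources, as real resources do
    status <- if (s %% 2L == 1L) {
      ifelse(obs[idx, s] == 1L, "withdrawn", "approved")
    } else {
      ifelse(obs[idx, s] == 1L, "discontinued", "marketed")
    }
    data.frame(id = sprintf("SYN%04d", idx), name = NA_character_,
               smiles = truth$smiles[idx], status = status,
               source = src_names[s], stringsAsFactors = FALSE)
  }))
  rownames(records) <- NULL
  list(databases = databases, truth = truth, records = records)
}

#' Status maps for the synthetic sources
#'
#' @param config a [synthetic_config()].
#' @return named list (per source) of status-map vectors suitable for
#'   [parse_drug_table()].
#' @export
synthetic_status_maps <- function(config) {
  S <- config$n_sources
  stats::setNames(lapply(seq_len(S), function(s) {
    if (s %% 2L == 1L) {
      c(withdrawn = "withdrawn", approved = "approved")
    } else {
      c(discontinued = "withdrawn", marketed = "approved")
    }
  }), paste0("source", seq_len(S)))
}

#' Generate a complete synthetic multi-source corpus
#'
#' Seeds the random number generator from `config$seed` and runs
#' [generate_molecules()], [assign_true_labels()] and
#' [distribute_to_sources()].
#'
#' @param config a [synthetic_config()].
#' @return list with `databases`, `truth`, `records`, `config`.
#' @export
synthetic_corpus <- function(config = synthetic_config()) {
  set.seed(config$seed)
  molecules <- generate_molecules(config)
  truth <- assign_true_labels(molecules, config)
  out <- distribute_to_sources(truth, config)
  out$config <- config
  out
}

#' Write a synthetic corpus as source CSV files plus ground truth
#'
#' One `<source>.csv` per source in the corpus-module input format and a
#' `ground_truth.csv` with true labels, fragment flags and per-source
#' observed labels.
#'
#' @param corpus result of [synthetic_corpus()].
#' @param dir output directory (created if missing).
#' @return the directory path, invisibly.
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (src in split(corpus$records, corpus$records$source)) {
    utils::write.csv(src, file.path(dir, paste0(src$source[1], ".csv")),
                     row.names = FALSE, na = "")
  }
  utils::write.csv(corpus$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, na = "")
  invisible(dir)
}
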