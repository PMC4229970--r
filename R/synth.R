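# Deterministic generator of synthetic protein families with the statistical
# structure the method assumes: each family is one mechanism with a
# characteristic signature set and a lineage of orthologous sequences;
# negatives are unlabeled proteins with sparse, mostly private signatures;
# optional confounder family pairs share signatures while differing in
# mechanism (the situation in which exact-signature transfer misannotates);
# optional complex families carry subunit sub-labels exercising the label
# split/truncate machinery. Empty anchor instances are appended as in the
# nearest-neighbour training protocol.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

#' Configuration for the synthetic family generator
#'
#' @param seed Mandatory integer seed; the same seed reproduces the output
#'   byte for byte.
#' @param n_families Number of protein families (one mechanism label each).
#' @param orthologs_per_family Sequences per family (per subunit for complex
#'   families).
#' @param signatures_per_family Mean signature count per family (minimum 4 is
#'   enforced so within-family distances stay informative).
#' @param signature_dropout Probability that an ortholog loses one signature
#'   of its family set (at most one per ortholog; see Details).
#' @param n_confounder_pairs Number of family pairs sharing signatures while
#'   differing in mechanism.
#' @param shared_signature_overlap Fraction of the first family's signatures
#'   reused by its confounder partner; at 1 the two families have identical
#'   signature sets and dropout is disabled for them, reproducing the
#'   exact-same-signatures misannotation case.
#' @param identity_band Sequence identity band `[lo, hi]` (fractions) that
#'   within-family ortholog pairs should land in.
#' @param n_negatives Unlabeled background proteins.
#' @param n_complex_families How many families are multi-subunit complexes.
#' @param subunits_per_complex Subunits per complex family.
#' @param length_band Sequence length band `[lo, hi]` (residues).
#' @param n_padding Empty anchor instances appended to the dataset.
#'
#' @details At most one signature is dropped per ortholog, so same-family
#' signature distances stay in `[0, sqrt(2)]` — a small but nonzero band —
#' while a query's distance to an empty anchor (`sqrt(>=3)`) and to other
#' families (disjoint signature pools) remains strictly larger. This is what
#' makes clean nearest-neighbour recovery exact and keeps negatives anchored
#' to the empty instances.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed, n_families = 5, orthologs_per_family = 3,
                         signatures_per_family = 6, signature_dropout = 0.1,
                         n_confounder_pairs = 0, shared_signature_overlap = 1,
                         identity_band = c(0.4, 0.9), n_negatives = 10,
                         n_complex_families = 0, subunits_per_complex = 2,
                         length_band = c(250, 400), n_padding = 2) {
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_families >= 1, orthologs_per_family >= 1,
            signatures_per_family >= 1, signature_dropout >= 0,
            signature_dropout <= 1, n_confounder_pairs >= 0,
            shared_signature_overlap >= 0, shared_signature_overlap <= 1,
            length(identity_band) == 2, identity_band[1] > 0,
            identity_band[2] <= 1, identity_band[1] <= identity_band[2],
            n_negatives >= 0, n_complex_families >= 0,
            n_complex_families <= n_families, subunits_per_complex >= 2,
            length(length_band) == 2, length_band[1] >= 30,
            n_padding >= 0)
  if (2 * n_confounder_pairs > n_families) {
    stop("not enough families for the requested confounder pairs")
  }
  # an identity target must be reachable by whole-residue substitutions
  if (identity_band[1] < 1 / length_band[1]) {
    stop("identity band unreachable at the configured sequence length")
  }
  structure(as.list(environment()), class = "synth_config")
}

random_sequence <- function(len) {
  paste(sample(AA20, len, replace = TRUE), collapse = "")
}

# orthologs from a common ancestor: nested substitution-position sets, so the
# pairwise identity of two orthologs is about the smaller of their two
# ancestor identities and every same-family pair stays inside the band
mutate_lineage <- function(ancestor, targets) {
  L <- nchar(ancestor)
  chars <- strsplit(ancestor, "")[[1]]
  m_counts <- pmin(L, round((1 - targets) * L))
  order_pos <- sample(L)               # one shared mutation order per family
  lapply(m_counts, function(m) {
    out <- chars
    if (m > 0) {
      pos <- order_pos[seq_len(m)]
      out[pos] <- vapply(out[pos], function(a) {
        sample(setdiff(AA20, a), 1)
      }, "")
    }
    paste(out, collapse = "")
  })
}

#' Generate a synthetic multi-label protein dataset
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_data` with elements `dataset` (an
#'   `ml_dataset` including the empty anchors), `store` (named character
#'   vector of sequences), `split_map` (data frame `original`/`protein`/
#'   `split`, or `NULL` without complex families; the dataset itself carries
#'   the original 5-character codes), `truth` (per-protein table: family,
#'   mechanism, subunit, negative/confounder flags, identity target) and
#'   `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(config$seed, {
    mech <- sprintf("M%04d", seq_len(config$n_families))
    confounded <- integer(0)
    partner <- rep(NA_integer_, config$n_families)
    if (config$n_confounder_pairs > 0) {
      for (p in seq_len(config$n_confounder_pairs)) {
        a <- 2 * p - 1; b <- 2 * p
        partner[a] <- b; partner[b] <- a
        confounded <- c(confounded, a, b)
      }
    }
    complexes <- utils::tail(seq_len(config$n_families),
                             config$n_complex_families)
    complexes <- setdiff(complexes, confounded)

    # family signature pools
    pool_size <- pmax(4L, stats::rpois(config$n_families,
                                       max(0, config$signatures_per_family - 4)) + 4L)
    fam_sigs <- lapply(seq_len(config$n_families), function(f) {
      sprintf("SIG_F%02d_%02d", f, seq_len(pool_size[f]))
    })
    full_overlap <- config$shared_signature_overlap >= 1
    for (f in seq_len(config$n_families)) {
      p <- partner[f]
      if (!is.na(p) && p < f) {        # second member of a confounder pair
        if (full_overlap) {
          fam_sigs[[f]] <- fam_sigs[[p]]
        } else {
          k <- round(config$shared_signature_overlap * length(fam_sigs[[p]]))
          keep <- length(fam_sigs[[f]]) - k
          fam_sigs[[f]] <- c(utils::head(fam_sigs[[p]], k),
                             utils::head(fam_sigs[[f]], max(1, keep)))
        }
      }
    }

    rows <- list(); seqs <- character(0); split_rows <- list()
    add_member <- function(id, fam, subunit, sigs, target, seq) {
      rows[[length(rows) + 1]] <<- list(
        protein = id, family = fam, mechanism = mech[fam],
        subunit = subunit, is_negative = FALSE,
        is_confounder = fam %in% confounded, identity_target = target,
        signatures = sigs)
      seqs[id] <<- seq
    }

    for (f in seq_len(config$n_families)) {
      subunits <- if (f %in% complexes) {
        sprintf("subunit_%s", LETTERS[seq_len(config$subunits_per_complex)])
      } else NA_character_
      for (s in seq_along(subunits)) {
        su <- subunits[s]
        sigs_base <- if (is.na(su)) fam_sigs[[f]] else {
          # each subunit lineage gets its own private signature block
          sprintf("SIG_F%02d%s_%02d", f, LETTERS[s], seq_len(pool_size[f]))
        }
        ancestor <- random_sequence(round(stats::runif(1, config$length_band[1],
                                                       config$length_band[2])))
        targets <- stats::runif(config$orthologs_per_family,
                                config$identity_band[1], config$identity_band[2])
        seqs_f <- mutate_lineage(ancestor, targets)
        for (o in seq_len(config$orthologs_per_family)) {
          id <- if (is.na(su)) sprintf("P_F%02d_%d", f, o) else
            sprintf("P_F%02d%s_%d", f, LETTERS[s], o)
          sigs <- sigs_base
          drop_ok <- !(f %in% confounded && full_overlap)
          if (drop_ok && length(sigs) > 3 &&
              stats::runif(1) < config$signature_dropout * length(sigs)) {
            sigs <- sigs[-sample(length(sigs), 1)]
          }
          add_member(id, f, su, sigs, targets[o], seqs_f[[o]])
          if (!is.na(su)) {
            split_rows[[length(split_rows) + 1]] <- data.frame(
              original = mech[f], protein = id,
              split = paste0(mech[f], "_", su), stringsAsFactors = FALSE)
          }
        }
      }
    }

    all_fam_sigs <- unique(unlist(fam_sigs))
    for (g in seq_len(config$n_negatives)) {
      id <- sprintf("P_NEG_%02d", g)
      sigs <- c(sample(all_fam_sigs, 1),
                sprintf("SIG_NEG%02d_%d", g, 1:2))
      len <- round(stats::runif(1, config$length_band[1], config$length_band[2]))
      rows[[length(rows) + 1]] <- list(
        protein = id, family = NA_integer_, mechanism = NA_character_,
        subunit = NA_character_, is_negative = TRUE, is_confounder = FALSE,
        identity_target = NA_real_, signatures = sigs)
      seqs[id] <- random_sequence(len)
    }

    ann <- do.call(rbind, lapply(rows, function(r) {
      data.frame(protein = r$protein, signature = r$signatures,
                 stringsAsFactors = FALSE)
    }))
    lab <- do.call(rbind, c(lapply(rows, function(r) {
      if (is.na(r$mechanism)) NULL else
        data.frame(protein = r$protein, label = r$mechanism,
                   stringsAsFactors = FALSE)
    }), list(NULL)))
    dataset <- build_dataset(ann, lab)
    dataset <- add_empty_instances(dataset, config$n_padding)
    truth <- do.call(rbind, lapply(rows, function(r) {
      data.frame(protein = r$protein, family = r$family,
                 mechanism = r$mechanism, subunit = r$subunit,
                 is_negative = r$is_negative, is_confounder = r$is_confounder,
                 identity_target = r$identity_target, stringsAsFactors = FALSE)
    }))
    split_map <- if (length(split_rows)) do.call(rbind, split_rows) else NULL
    structure(list(dataset = dataset, store = seqs, split_map = split_map,
                   truth = truth, config = config),
              class = "synth_data")
  })
}

#' @export
print.synth_data <- function(x, ...) {
  cat(sprintf(
    "synth_data: %d labeled + %d negative instances (+%d anchors), %d mechanisms, seed %d\n",
    sum(!x$truth$is_negative), sum(x$truth$is_negative),
    sum(x$dataset$padding), length(x$dataset$label_space), x$config$seed))
  invisible(x)
}

#' Mutate a sequence towards a target global identity
#'
#' Applies random point substitutions (plus, optionally, a few single-residue
#' indels) and iteratively adjusts the substitution count until the global
#' alignment identity of the mutant against the original is within `tol` of
#' `target_identity`.
#'
#' @param seq Amino-acid sequence.
#' @param target_identity Target identity in `(0, 1]`; 1 returns the input
#'   unchanged.
#' @param seed Integer seed (different seeds give different mutants at the
#'   same target).
#' @param indel_rate Fraction of positions subject to single-residue
#'   insertions/deletions (capped at 0.05).
#' @param tol Acceptable deviation from the target.
#' @param max_iter Iteration cap; exceeded → generation error.
#' @param params [alignment_params()] used to measure identity.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(seq, target_identity, seed, indel_rate = 0,
                            tol = 0.02, max_iter = 40,
                            params = alignment_params()) {
  stopifnot(target_identity > 0, target_identity <= 1, indel_rate <= 0.05,
            indel_rate >= 0)
  if (target_identity == 1) return(seq)
  local_seed(seed, {
    L <- nchar(seq)
    chars <- strsplit(toupper(seq), "")[[1]]
    m <- round((1 - target_identity) * L)
    for (it in seq_len(max_iter)) {
      out <- chars
      pos <- sample(L, min(L, max(0, m)))
      out[pos] <- vapply(out[pos], function(a) sample(setdiff(AA20, a), 1), "")
      if (indel_rate > 0) {
        n_indel <- round(indel_rate * L)
        for (z in seq_len(n_indel)) {
          if (stats::runif(1) < 0.5 && length(out) > 30) {
            out <- out[-sample(length(out), 1)]
          } else {
            at <- sample(length(out), 1)
            out <- append(out, sample(AA20, 1), after = at)
          }
        }
      }
      cand <- paste(out, collapse = "")
      got <- pairwise_identity(seq, cand, params)
      if (abs(got - target_identity) <= tol) return(cand)
      m <- m + round((got - target_identity) * L)
      m <- max(0, min(L, m))
    }
    stop("mutate_sequence: target identity ", target_identity,
         " unreachable within ", max_iter, " iterations")
  })
}
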