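# Synthetic miRNA-disease networks with planted low-rank structure.
#
# The generator emulates the statistical structure the recovery model
# assumes: association profiles that are (noisy thresholdings of) a
# low-rank nonnegative product U V', miRNA families whose members share
# latent profiles, and similarity matrices consistent with the latent
# factors (cosine of U rows for the functional side, of V rows for the
# semantic side). The pre-threshold score matrix P = U V' is returned as
# ground truth for rank-correlation checks.

#' Configuration for the synthetic network generator
#'
#' Defaults define the package's reference study conditions: a 40 x 25
#' network of planted rank 3 at 12% association density, 8 miRNA families
#' with high within-family coherence, and a small entry-flip noise rate.
#'
#' @param m,n Numbers of miRNAs and diseases.
#' @param rank Planted latent rank (`<= min(m, n)`).
#' @param density Expected fraction of 1-entries, in (0, 1); `density * m *
#'   n` must be at least 2.
#' @param n_families Number of miRNA families.
#' @param family_coherence Probability that a family member adopts its
#'   family's shared latent profile rather than an individual draw.
#' @param noise_flip Probability of flipping each association entry.
#' @param seed Integer seed; the generator is fully determined by it.
#' @return A list of class `ilrmr_synth_config`.
#' @export
synth_config <- function(m = 40L, n = 25L, rank = 3L, density = 0.12,
                         n_families = 8L, family_coherence = 0.8,
                         noise_flip = 0.01, seed = 1L) {
  if (rank > min(m, n)) stop("rank must not exceed min(m, n)", call. = FALSE)
  if (density <= 0 || density >= 1) stop("density must be in (0, 1)", call. = FALSE)
  if (density * m * n < 2) {
    stop("infeasible density: fewer than 2 expected associations", call. = FALSE)
  }
  if (family_coherence < 0 || family_coherence > 1) {
    stop("family_coherence must be in [0, 1]", call. = FALSE)
  }
  if (noise_flip < 0 || noise_flip >= 1) {
    stop("noise_flip must be in [0, 1)", call. = FALSE)
  }
  structure(list(m = as.integer(m), n = as.integer(n), rank = as.integer(rank),
                 density = density, n_families = as.integer(n_families),
                 family_coherence = family_coherence, noise_flip = noise_flip,
                 seed = as.integer(seed)),
            class = "ilrmr_synth_config")
}

#' Generate a synthetic miRNA-disease network
#'
#' Draws nonnegative latent factors `U` (miRNAs) and `V` (diseases) as
#' absolute-valued normals (so cosine similarities land in \[0, 1\] without
#' rescaling), lets family members share `U` rows with probability
#' `family_coherence`, thresholds `P = U V'` at the quantile matching the
#' target density, and flips each entry with probability `noise_flip`.
#'
#' @param config A [synth_config()].
#' @return A list: `assoc` ([association_matrix()]), `sim_mir_fun`
#'   (functional similarity from U), `sim_dd_phe` (semantic similarity from
#'   V), `fams` ([family_assignment()]), `ground_truth` (the pre-threshold
#'   P), and `config`.
#' @export
generate_network <- function(config = synth_config()) {
  stopifnot(inherits(config, "ilrmr_synth_config"))
  set.seed(config$seed)
  m <- config$m; n <- config$n; r <- config$rank
  mirna_ids <- sprintf("mir-%03d", seq_len(m))
  disease_ids <- sprintf("disease-%02d", seq_len(n))

  fam_labels <- sprintf("fam-%02d", seq_len(config$n_families))
  fam_of_mirna <- sample(fam_labels, m, replace = TRUE)
  fam_profiles <- matrix(abs(stats::rnorm(config$n_families * r)),
                         config$n_families, r)
  U <- matrix(abs(stats::rnorm(m * r)), m, r)
  coherent <- stats::runif(m) < config$family_coherence
  U[coherent, ] <- fam_profiles[match(fam_of_mirna, fam_labels)[coherent], ,
                                drop = FALSE]
  V <- matrix(abs(stats::rnorm(n * r)), n, r)

  P <- U %*% t(V)
  thr <- stats::quantile(P, probs = 1 - config$density, names = FALSE)
  A <- (P > thr) * 1
  if (config$noise_flip > 0) {
    flips <- stats::runif(m * n) < config$noise_flip
    A[flips] <- 1 - A[flips]
  }
  dimnames(P) <- list(mirna_ids, disease_ids)

  list(
    assoc = association_matrix(A, mirna_ids, disease_ids),
    sim_mir_fun = similarity_matrix(cosine_rows(U), mirna_ids,
                                    kind = "mirna_functional"),
    sim_dd_phe = similarity_matrix(cosine_rows(V), disease_ids,
                                   kind = "disease_semantic"),
    fams = family_assignment(mirna_ids, fam_of_mirna),
    ground_truth = P,
    config = config
  )
}

#' Generate a planted low-rank-plus-sparse test instance
#'
#' `R0` is an exact rank-`rank` product of Gaussian factors; `E0` places
#' `round(spike_fraction * m * n)` spikes of magnitude `spike_magnitude`
#' with random signs at uniformly chosen positions; `X = R0 + E0`.
#'
#' @param m,n Matrix dimensions.
#' @param rank Exact rank of the low-rank part (`<= min(m, n)`).
#' @param spike_fraction Fraction of entries carrying a spike.
#' @param spike_magnitude Absolute value of each spike.
#' @param seed Integer seed.
#' @return A list with `X`, `R0`, `E0`.
#' @export
generate_lowrank_sparse <- function(m, n, rank, spike_fraction = 0.05,
                                    spike_magnitude = 1, seed = 1L) {
  if (rank > min(m, n)) stop("rank must not exceed min(m, n)", call. = FALSE)
  if (spike_fraction < 0) stop("spike_fraction must be nonnegative", call. = FALSE)
  set.seed(seed)
  R0 <- matrix(stats::rnorm(m * rank), m, rank) %*%
    matrix(stats::rnorm(rank * n), rank, n)
  E0 <- matrix(0, m, n)
  n_spikes <- round(spike_fraction * m * n)
  if (n_spikes > 0) {
    pos <- sample(m * n, n_spikes)
    E0[pos] <- spike_magnitude * sample(c(-1, 1), n_spikes, replace = TRUE)
  }
  list(X = R0 + E0, R0 = R0, E0 = E0)
}

#' Write a generated network to a directory in the package's TSV formats
#'
#' Writes `associations.tsv` (dense 0/1 matrix — the dense format is used so
#' that miRNAs and diseases without any association survive the round trip),
#' `sim_mirna.tsv`, `sim_disease.tsv`, `families.tsv`, `ground_truth.tsv`
#' and a JSON `manifest.json` recording the configuration.
#'
#' @param net Output of [generate_network()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(net$assoc, file.path(dir, "associations.tsv"))
  write_matrix(net$sim_mir_fun, file.path(dir, "sim_mirna.tsv"))
  write_matrix(net$sim_dd_phe, file.path(dir, "sim_disease.tsv"))
  writeLines(paste(names(net$fams), unclass(net$fams), sep = "\t"),
             file.path(dir, "families.tsv"))
  write_matrix(net$ground_truth, file.path(dir, "ground_truth.tsv"))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    c(unclass(net$config),
      list(association_format = "dense",
           files = list(associations = "associations.tsv",
                        sim_mirna = "sim_mirna.tsv",
                        sim_disease = "sim_disease.tsv",
                        families = "families.tsv",
                        ground_truth = "ground_truth.tsv"))),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
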