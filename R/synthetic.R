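# Simulators for every input the pipeline consumes: a patient+healthy screen
# with two planted drug clusters, a cluster-biased drug-target map,
# cluster-correlated binary fingerprints, and Hill-based dose-response
# surfaces with configurable interaction structure.

#' Specification of a synthetic drug-response screen
#'
#' The generator plants two drug clusters with distinct mean response
#' profiles across patient samples. Patient samples alternate between two
#' response subtypes; cluster-1 drugs respond above baseline on subtype-1
#' samples and below on subtype-2 samples, cluster-2 drugs the opposite. The
#' per-sample gap between the two cluster profiles is `profile_separation`
#' noise standard deviations, so separation is expressed as an effect size.
#' Healthy-sample responses are the drug's patient-level mean attenuated by
#' `healthy_attenuation` (low values emulate low-toxicity drugs). All
#' responses are truncated to \[0, 1\].
#'
#' Missingness: under the default `"panel"` mechanism drugs are grouped into
#' `n_panels` assay panels and whole sample-by-panel blocks are untested,
#' with the number of missing blocks chosen so the overall missing-cell
#' density equals `missing_rate`. This emulates how screening data actually
#' go missing (a sample is simply not run against a panel) and is what makes
#' large complete submatrices recoverable, as in real screens.
#' `"iid"` masks cells independently with probability `missing_rate` instead.
#'
#' @param n_patient,n_healthy sample counts (>= 1).
#' @param n_drugs_per_cluster integer pair, drugs in each planted cluster.
#' @param profile_separation effect size d >= 0 separating the cluster mean
#'   profiles, in units of `noise_sd`.
#' @param noise_sd response-scale Gaussian noise SD (> 0).
#' @param missing_rate expected missing-cell density in \[0, 1).
#' @param healthy_attenuation multiplier in \[0, 1\] applied to responses on
#'   healthy samples.
#' @param missing_mechanism `"panel"` (structured, default) or `"iid"`.
#' @param n_panels number of drug panels for the panel mechanism.
#' @param seed integer RNG seed; identical specs give bit-identical screens.
#'
#' @return A `screen_spec` list.
#' @export
screen_spec <- function(n_patient = 40, n_healthy = 10,
                        n_drugs_per_cluster = c(20, 20),
                        profile_separation = 6, noise_sd = 0.1,
                        missing_rate = 0.2, healthy_attenuation = 0.3,
                        missing_mechanism = c("panel", "iid"),
                        n_panels = 4, seed = 1) {
  missing_mechanism <- match.arg(missing_mechanism)
  spec <- list(
    n_patient = check_count(n_patient, "n_patient"),
    n_healthy = check_count(n_healthy, "n_healthy"),
    n_drugs_per_cluster = c(
      check_count(n_drugs_per_cluster[1], "n_drugs_per_cluster"),
      check_count(n_drugs_per_cluster[2], "n_drugs_per_cluster")
    ),
    profile_separation = {
      if (!is.numeric(profile_separation) || profile_separation < 0) {
        stop_field("profile_separation", "must be >= 0")
      }
      as.numeric(profile_separation)
    },
    noise_sd = {
      if (!is.numeric(noise_sd) || noise_sd <= 0) {
        stop_field("noise_sd", "must be > 0")
      }
      as.numeric(noise_sd)
    },
    missing_rate = check_prob(missing_rate, "missing_rate", hi = 1, hi_open = TRUE),
    healthy_attenuation = check_prob(healthy_attenuation, "healthy_attenuation"),
    missing_mechanism = missing_mechanism,
    n_panels = check_count(n_panels, "n_panels"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(n_drugs_per_cluster) != 2L) {
    stop_field("n_drugs_per_cluster", "must be a pair of counts")
  }
  structure(spec, class = "screen_spec")
}

#' Simulate a patient + healthy drug-response screen with planted clusters
#'
#' @param spec a [screen_spec()].
#' @return A [raw_screen] whose `drug_cluster` field carries the planted
#'   cluster labels (1 or 2) for recovery scoring.
#' @export
simulate_screen <- function(spec) {
  stopifnot(inherits(spec, "screen_spec"))
  with_seed(spec$seed, {
    n_s <- spec$n_patient + spec$n_healthy
    n_d <- sum(spec$n_drugs_per_cluster)
    cluster <- rep(1:2, times = spec$n_drugs_per_cluster)
    # balanced alternation of the two patient response subtypes
    sign_p <- rep(c(1, -1), length.out = spec$n_patient)
    half_gap <- spec$profile_separation * spec$noise_sd / 2
    # mild drug-level potency variation on top of the cluster profile
    drug_offset <- stats::rnorm(n_d, 0, spec$noise_sd / 2)

    vals <- matrix(NA_real_, n_s, n_d)
    for (j in seq_len(n_d)) {
      s_g <- if (cluster[j] == 1L) 1 else -1
      mu_pat <- 0.5 + s_g * sign_p * half_gap + drug_offset[j]
      vals[seq_len(spec$n_patient), j] <-
        mu_pat + stats::rnorm(spec$n_patient, 0, spec$noise_sd)
      mu_healthy <- spec$healthy_attenuation * mean(mu_pat)
      vals[spec$n_patient + seq_len(spec$n_healthy), j] <-
        mu_healthy + stats::rnorm(spec$n_healthy, 0, spec$noise_sd)
    }
    vals <- matrix(clamp01(vals), n_s, n_d)
    if (spec$missing_rate > 0) {
      if (spec$missing_mechanism == "iid") {
        mask <- matrix(stats::runif(n_s * n_d) < spec$missing_rate, n_s, n_d)
      } else {
        # structured missingness: whole sample x panel blocks untested;
        # block count fixed so the realized density matches missing_rate
        panel <- rep(seq_len(spec$n_panels), length.out = n_d)
        n_blocks <- n_s * spec$n_panels
        n_miss <- round(spec$missing_rate * n_blocks)
        hit <- sample.int(n_blocks, n_miss)
        mask <- matrix(FALSE, n_s, n_d)
        for (h in hit) {
          s <- (h - 1L) %/% spec$n_panels + 1L
          p <- (h - 1L) %% spec$n_panels + 1L
          mask[s, panel == p] <- TRUE
        }
      }
      vals[mask] <- NA_real_
    }
    raw_screen(
      values = vals,
      sample_class = rep(c("patient", "healthy"),
                         c(spec$n_patient, spec$n_healthy)),
      sample_ids = sprintf("%s%03d",
                           rep(c("AML_", "H_"), c(spec$n_patient, spec$n_healthy)),
                           c(seq_len(spec$n_patient), seq_len(spec$n_healthy))),
      drug_ids = sprintf("D%03d", seq_len(n_d)),
      drug_cluster = cluster
    )
  })
}

#' Simulate a cluster-biased drug-to-protein-target map
#'
#' Proteins are split into two equal pools; a drug from planted cluster g
#' draws each of its targets from pool g with probability `bias` and from the
#' other pool otherwise. `bias = 0.5` gives no cluster preference,
#' `bias = 1` makes the pools exclusive.
#'
#' @param cluster_labels integer vector of planted cluster (1/2) per drug,
#'   named by drug id (unnamed labels get generated ids).
#' @param n_proteins total protein universe size (split into two pools).
#' @param bias probability in \[0.5, 1\] of drawing from the own-cluster pool.
#' @param n_targets_per_drug distinct targets per drug.
#' @param seed integer RNG seed.
#'
#' @return A named list mapping drug id to a character vector of protein ids,
#'   with attribute `pools` (list of the two protein pools).
#' @export
simulate_target_map <- function(cluster_labels, n_proteins = 100, bias = 0.9,
                                n_targets_per_drug = 5, seed = 1) {
  bias <- check_prob(bias, "bias", lo = 0.5)
  n_proteins <- check_count(n_proteins, "n_proteins", min = 2L)
  n_targets_per_drug <- check_count(n_targets_per_drug, "n_targets_per_drug")
  if (is.null(names(cluster_labels))) {
    names(cluster_labels) <- sprintf("D%03d", seq_along(cluster_labels))
  }
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  half <- n_proteins %/% 2L
  pools <- list(proteins[seq_len(half)], proteins[(half + 1L):n_proteins])
  with_seed(seed, {
    map <- lapply(names(cluster_labels), function(d) {
      g <- cluster_labels[[d]]
      own <- stats::rbinom(n_targets_per_drug, 1L, bias) == 1L
      pool_idx <- ifelse(own, g, 3L - g)
      tgt <- character(n_targets_per_drug)
      for (k in seq_len(n_targets_per_drug)) {
        tgt[k] <- sample(pools[[pool_idx[k]]], 1L)
      }
      unique(tgt)
    })
    names(map) <- names(cluster_labels)
    attr(map, "pools") <- pools
    map
  })
}

# expected Dice between two independent bit-flipped copies of a seed
# fingerprint of density p, each bit flipped with probability q
.flip_dice <- function(q, p) {
  (p * (1 - q)^2 + (1 - p) * q^2) / (p + q - 2 * p * q)
}

#' Simulate cluster-correlated binary fingerprints
#'
#' Each cluster has a random seed fingerprint of density `density`; members
#' are independent bit-flipped copies with the flip probability tuned so that
#' the expected intra-cluster Dice similarity equals `within_similarity`.
#' Members of different clusters descend from independent seeds, so the
#' expected inter-cluster Dice is approximately `density`, strictly below
#' `within_similarity`. The flip construction can reach any expected Dice in
#' (0.5, 1\]; values at or below 0.5 are indistinguishable from independent
#' fingerprints and are rejected.
#'
#' @param cluster_labels integer vector of cluster (1/2) per drug, optionally
#'   named by drug id.
#' @param n_bits fingerprint length (>= 8).
#' @param within_similarity target expected intra-cluster Dice in (0.5, 1\].
#' @param density expected fraction of ON bits (default 0.5).
#' @param seed integer RNG seed.
#'
#' @return A named list of sorted integer on-bit positions (0-based), with
#'   attribute `n_bits`.
#' @export
simulate_fingerprints <- function(cluster_labels, n_bits = 1024,
                                  within_similarity = 0.8, density = 0.5,
                                  seed = 1) {
  n_bits <- check_count(n_bits, "n_bits", min = 8L)
  density <- check_prob(density, "density", lo = 0, hi = 1,
                        lo_open = TRUE, hi_open = TRUE)
  if (!is.numeric(within_similarity) || length(within_similarity) != 1L ||
      within_similarity <= 0) {
    stop_field("within_similarity", "must be in (0, 1]")
  }
  floor_dice <- .flip_dice(0.5, density)  # = 0.5: fully randomized copies
  if (within_similarity <= floor_dice || within_similarity > 1) {
    stop_field("within_similarity", sprintf(
      "unreachable: expected intra-cluster Dice of the flip construction lies in (%.2f, 1]",
      floor_dice
    ))
  }
  q <- if (within_similarity == 1) 0 else {
    stats::uniroot(function(q) .flip_dice(q, density) - within_similarity,
                   c(1e-9, 0.5 - 1e-9), tol = 1e-10)$root
  }
  if (is.null(names(cluster_labels))) {
    names(cluster_labels) <- sprintf("D%03d", seq_along(cluster_labels))
  }
  with_seed(seed, {
    seeds <- lapply(1:2, function(g) stats::runif(n_bits) < density)
    fps <- lapply(names(cluster_labels), function(d) {
      base <- seeds[[cluster_labels[[d]]]]
      flip <- stats::runif(n_bits) < q
      bits <- xor(base, flip)
      if (!any(bits)) bits[sample.int(n_bits, 1L)] <- TRUE
      sort(which(bits) - 1L)
    })
    names(fps) <- names(cluster_labels)
    attr(fps, "n_bits") <- n_bits
    fps
  })
}

#' Specification of a synthetic dose-response combination surface
#'
#' Monotherapy responses follow the two Hill curves exactly (plus optional
#' replicate noise); each combination cell equals the chosen null model's
#' expectation plus `shift_delta` plus noise, truncated to \[0, 1\]. The
#' interaction modes are `bliss_independent` (probabilistic independence),
#' `hsa_max` (highest single agent), `sham_self` (dose additivity of a drug
#' with itself: response at dose xa + xb of curve A), and `additive_shift`
#' (general Loewe dose-additive expectation of the two curves).
#'
#' @param hill_a,hill_b [hill_params()] of the two monotherapy curves.
#' @param dose_grid strictly increasing positive doses (nM); default the
#'   five-point ladder 1, 10, 100, 1000, 10000.
#' @param interaction interaction null used for combination cells.
#' @param shift_delta response-fraction offset in \[-1, 1\] added to the null
#'   expectation (positive = synergy planted on top of the null).
#' @param replicate_noise_sd response-scale noise SD (0 = noise free).
#' @param seed integer RNG seed.
#' @export
surface_spec <- function(hill_a = hill_params(), hill_b = hill_params(),
                         dose_grid = c(1, 10, 100, 1000, 10000),
                         interaction = c("bliss_independent", "hsa_max",
                                         "sham_self", "additive_shift"),
                         shift_delta = 0, replicate_noise_sd = 0, seed = 1) {
  interaction <- match.arg(interaction)
  if (any(dose_grid <= 0) || is.unsorted(dose_grid, strictly = TRUE)) {
    stop_field("dose_grid", "must be strictly increasing positive doses")
  }
  if (!is.numeric(shift_delta) || abs(shift_delta) > 1) {
    stop_field("shift_delta", "must be in [-1, 1]")
  }
  if (!is.numeric(replicate_noise_sd) || replicate_noise_sd < 0) {
    stop_field("replicate_noise_sd", "must be >= 0")
  }
  structure(
    list(hill_a = hill_a, hill_b = hill_b, dose_grid = as.numeric(dose_grid),
         interaction = interaction, shift_delta = as.numeric(shift_delta),
         replicate_noise_sd = as.numeric(replicate_noise_sd),
         seed = check_count(seed, "seed", min = 0L)),
    class = "surface_spec"
  )
}

#' Simulate a dose-response combination surface
#'
#' @param spec a [surface_spec()].
#' @param drug_a,drug_b drug ids attached to the surface.
#' @return A [dose_response_surface].
#' @export
simulate_surface <- function(spec, drug_a = "drugA", drug_b = "drugB") {
  stopifnot(inherits(spec, "surface_spec"))
  d <- spec$dose_grid
  with_seed(spec$seed, {
    ya <- hill_response(d, spec$hill_a)
    yb <- hill_response(d, spec$hill_b)
    expect <- switch(spec$interaction,
      bliss_independent = outer(ya, yb, function(a, b) a + b - a * b),
      hsa_max = outer(ya, yb, pmax),
      sham_self = outer(d, d, function(xa, xb) hill_response(xa + xb, spec$hill_a)),
      additive_shift = outer(seq_along(d), seq_along(d), Vectorize(function(i, j) {
        loewe_expected(d[i], d[j], spec$hill_a, spec$hill_b)$y
      }))
    )
    noise <- function(n) {
      if (spec$replicate_noise_sd > 0) stats::rnorm(n, 0, spec$replicate_noise_sd) else 0
    }
    combo <- clamp01(expect + spec$shift_delta + noise(length(expect)))
    dose_response_surface(
      drug_a = drug_a, drug_b = drug_b, doses_a = d, doses_b = d,
      mono_a = clamp01(ya + noise(length(d))),
      mono_b = clamp01(yb + noise(length(d))),
      combo = matrix(combo, length(d), length(d))
    )
  })
}
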