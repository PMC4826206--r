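## Synthetic cohort generator: planted patient subtypes in two expression
## views, subtype-dependent exponential survival with independent censoring,
## and planted altered modules on a preferential-attachment interaction
## network. Every downstream stage of the pipeline has a ground truth here.

#' Simulate a multi-view cohort with planted subtypes
#'
#' Each view is baseline Gaussian noise with standard deviation `noise_sd`.
#' The first `n_informative[v]` features of view `v` are informative: they
#' are assigned round-robin to the subtypes, and for patients of the matching
#' subtype their mean is shifted by `effect_size * noise_sd`. Patients are
#' split across subtypes as evenly as possible.
#'
#' @param n_patients Number of patients.
#' @param n_subtypes Number of planted subtypes.
#' @param n_features Integer vector, number of features per view.
#' @param n_informative Integer vector, informative features per view
#'   (elementwise \code{<= n_features}).
#' @param effect_size Mean shift in units of `noise_sd` (must be >= 0).
#' @param noise_sd Noise standard deviation (> 0).
#' @param seed Optional RNG seed.
#' @return A list with `views` (list of patients-by-features matrices) and
#'   `truth` (list with `labels`, a named integer vector, and
#'   `informative_features`, per view a list of feature ids per subtype).
#' @export
simulate_cohort <- function(n_patients = 60L, n_subtypes = 2L,
                            n_features = c(200L, 200L),
                            n_informative = c(40L, 40L),
                            effect_size = 2, noise_sd = 1, seed = NULL) {
  check_scalar(n_patients, "n_patients", lower = 1, integer = TRUE)
  check_scalar(n_subtypes, "n_subtypes", lower = 1, integer = TRUE)
  if (n_subtypes > n_patients) stopf("more subtypes than patients")
  check_scalar(effect_size, "effect_size", lower = 0)
  check_scalar(noise_sd, "noise_sd", lower = 0, open_lower = TRUE)
  if (length(n_features) != length(n_informative)) {
    stopf("'n_features' and 'n_informative' must have the same length")
  }
  if (any(n_informative > n_features)) {
    stopf("'n_informative' exceeds 'n_features'")
  }
  patients <- sprintf("P%03d", seq_len(n_patients))
  labels <- rep_len(seq_len(n_subtypes), n_patients)
  names(labels) <- patients
  with_seed(seed, {
    views <- vector("list", length(n_features))
    informative <- vector("list", length(n_features))
    for (v in seq_along(n_features)) {
      p <- n_features[[v]]
      feats <- sprintf("V%dF%04d", v, seq_len(p))
      x <- matrix(stats::rnorm(n_patients * p, sd = noise_sd),
                  nrow = n_patients, dimnames = list(patients, feats))
      inf_sub <- rep_len(seq_len(n_subtypes), n_informative[[v]])
      for (k in seq_len(n_subtypes)) {
        fk <- which(inf_sub == k)
        if (length(fk) > 0L) {
          x[labels == k, fk] <- x[labels == k, fk] + effect_size * noise_sd
        }
      }
      views[[v]] <- x
      informative[[v]] <- split(feats[seq_len(n_informative[[v]])], inf_sub)
    }
    names(views) <- paste0("view", seq_along(views))
    list(views = views,
         truth = list(labels = labels, informative_features = informative))
  })
}

#' Simulate overall survival with subtype-dependent hazards
#'
#' Event times are exponential with the patient's subtype hazard. Censoring
#' times are independent exponential, with the censoring rate parameter
#' solved numerically so that the expected censored fraction equals
#' `censor_rate`; a patient is censored when the censoring time precedes the
#' event time.
#'
#' @param labels Named integer vector, patient to subtype index.
#' @param hazards Positive numeric vector, one hazard per subtype (per day).
#' @param censor_rate Target expected censored fraction in \[0, 1).
#' @param seed Optional RNG seed.
#' @return A clinical data frame with `patient_id`, `os_time`, `os_event`.
#' @export
simulate_survival <- function(labels, hazards, censor_rate = 0.2,
                              seed = NULL) {
  if (is.null(names(labels))) stopf("'labels' must be a named vector")
  if (any(!labels %in% seq_along(hazards))) {
    stopf("every patient must have a hazard for its subtype")
  }
  if (any(hazards <= 0) || any(!is.finite(hazards))) {
    stopf("'hazards' must be positive and finite")
  }
  check_scalar(censor_rate, "censor_rate", lower = 0, upper = 1,
               open_upper = TRUE)
  h <- hazards[labels]
  with_seed(seed, {
    tt <- stats::rexp(length(h), rate = h)
    if (censor_rate == 0) {
      os_time <- tt
      os_event <- rep(1L, length(h))
    } else {
      ## E[censored fraction] = mean_i c / (c + h_i); solve for c
      f <- function(cc) mean(cc / (cc + h)) - censor_rate
      cc <- stats::uniroot(f, lower = min(h) * 1e-8,
                           upper = max(h) * 1e8, tol = 1e-12)$root
      cens <- stats::rexp(length(h), rate = cc)
      os_event <- as.integer(tt <= cens)
      os_time <- pmin(tt, cens)
    }
    data.frame(patient_id = names(labels), os_time = os_time,
               os_event = os_event, stringsAsFactors = FALSE)
  })
}

#' Simulate an interaction network with planted altered modules
#'
#' Builds a preferential-attachment-style gene interaction graph and plants,
#' for each subtype, `modules_per_subtype` disjoint connected modules of
#' `module_size` genes (connectivity is guaranteed by adding a random
#' spanning tree among the module's genes). Beyond the tree, each remaining
#' within-module gene pair is wired with probability `module_density`, so a
#' planted module is not only connected but cohesive -- a bare tree admits
#' higher-modularity splits, and module detection would legitimately
#' fragment it. The binary alteration matrix has independent Bernoulli
#' entries: rate `alt_rate_in` for a planted gene in a patient of the
#' matching subtype, `alt_rate_bg` everywhere else.
#'
#' @param labels Named integer vector, patient to subtype index.
#' @param n_genes Number of genes in the network.
#' @param module_size Genes per planted module.
#' @param modules_per_subtype Planted modules per subtype.
#' @param alt_rate_in Alteration rate inside planted (gene, matching-subtype
#'   patient) cells; must exceed `alt_rate_bg`.
#' @param alt_rate_bg Background alteration rate.
#' @param module_density Probability of each non-tree within-module edge.
#' @param pa_edges Edges added per vertex during preferential attachment.
#' @param seed Optional RNG seed.
#' @return A list with `network` (igraph), `alterations` (binary
#'   genes-by-patients matrix over all patients) and `planted_modules`
#'   (per subtype, a list of gene-id vectors).
#' @export
simulate_network_alterations <- function(labels, n_genes = 500L,
                                         module_size = 12L,
                                         modules_per_subtype = 2L,
                                         alt_rate_in = 0.4,
                                         alt_rate_bg = 0.02,
                                         module_density = 0.4,
                                         pa_edges = 2L, seed = NULL) {
  check_scalar(n_genes, "n_genes", lower = 1, integer = TRUE)
  check_scalar(module_size, "module_size", lower = 1, integer = TRUE)
  check_scalar(modules_per_subtype, "modules_per_subtype", lower = 1,
               integer = TRUE)
  check_scalar(alt_rate_in, "alt_rate_in", lower = 0, upper = 1,
               open_lower = TRUE)
  check_scalar(alt_rate_bg, "alt_rate_bg", lower = 0, upper = 1,
               open_upper = TRUE)
  if (alt_rate_in <= alt_rate_bg) {
    stopf("'alt_rate_in' must exceed 'alt_rate_bg'")
  }
  check_scalar(module_density, "module_density", lower = 0, upper = 1)
  n_subtypes <- max(labels)
  n_planted <- module_size * modules_per_subtype * n_subtypes
  if (n_planted > n_genes) stopf("planted modules need more genes than 'n_genes'")
  genes <- sprintf("G%04d", seq_len(n_genes))
  with_seed(seed, {
    g <- igraph::sample_pa(n_genes, power = 1, m = pa_edges,
                           directed = FALSE)
    igraph::V(g)$name <- genes
    ## plant disjoint modules, each made connected by a random spanning tree
    pool <- sample(genes, n_planted)
    planted <- vector("list", n_subtypes)
    idx <- 0L
    extra_edges <- list()
    for (s in seq_len(n_subtypes)) {
      planted[[s]] <- vector("list", modules_per_subtype)
      for (m in seq_len(modules_per_subtype)) {
        mod <- pool[idx + seq_len(module_size)]
        idx <- idx + module_size
        ord <- sample(mod)
        if (module_size > 1L) {
          to <- vapply(2:module_size,
                       function(i) ord[sample.int(i - 1L, 1L)], "")
          tree <- rbind(ord[2:module_size], to)
          pairs <- utils::combn(sort(mod), 2L)
          in_tree <- paste(pmin(tree[1L, ], tree[2L, ]),
                           pmax(tree[1L, ], tree[2L, ]))
          free <- pairs[, !(paste(pairs[1L, ], pairs[2L, ]) %in% in_tree),
                        drop = FALSE]
          add <- free[, stats::runif(ncol(free)) < module_density,
                      drop = FALSE]
          extra_edges[[length(extra_edges) + 1L]] <- cbind(tree, add)
        }
        planted[[s]][[m]] <- sort(mod)
      }
    }
    if (length(extra_edges) > 0L) {
      ev <- as.vector(do.call(cbind, extra_edges))
      g <- igraph::add_edges(g, ev)
    }
    g <- igraph::simplify(g)
    ## Bernoulli alteration matrix over all patients
    rate <- matrix(alt_rate_bg, nrow = n_genes, ncol = length(labels),
                   dimnames = list(genes, names(labels)))
    for (s in seq_len(n_subtypes)) {
      sg <- unlist(planted[[s]])
      rate[sg, labels == s] <- alt_rate_in
    }
    x <- matrix(as.integer(stats::runif(length(rate)) < rate),
                nrow = n_genes, dimnames = dimnames(rate))
    list(network = g, alterations = x, planted_modules = planted)
  })
}
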