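# Synthetic study generator: produces an ASV table, taxonomy, sample
# metadata, a tree, and ground-truth compositions with the statistical
# structure the analysis assumes (mats > external > internal diversity;
# host-driven internal vs environment-driven external composition).

.GENUS_POOL <- c("Tychonema", "Larkinella", "Flavobacterium", "Polaromonas",
                 "Phormidesmis", "Nostoc", "Pseudanabaena", "Hymenobacter",
                 "Sphingomonas", "Rhodoferax", "Janthinobacterium",
                 "Cryobacterium", "Arthrobacter", "Gemmatimonas")
.PHYLUM_POOL <- c("Cyanobacteria", "Bacteroidota", "Proteobacteria",
                  "Actinobacteriota", "Gemmatimonadota", "Verrucomicrobiota")
.DEFAULT_HOSTS <- c("E_antarcticus", "P_murrayi", "Tardigrada")
.DEFAULT_STREAMS <- c("Canada", "BowlesCreek", "Delta", "VonGuerard")

#' Parameters of the synthetic study generator
#'
#' Defaults emulate the Dry Valley stream study design: 4 streams x 2 mat
#' types (black, orange) x 3 replicates = 24 mat samples; 3 host taxa with
#' washed and unwashed individuals per mat replicate; host reads mixed into
#' individual samples; and a diversity/selection gradient mats > external >
#' internal. Individual counts are scaled down from the study's hundreds of
#' specimens to `n_washed = n_unwashed = 2` per replicate and host for
#' desk-scale runtime; full-scale counts are reachable through the
#' parameters.
#'
#' @param n_streams,mat_types,replicates_per_mat,hosts design dimensions.
#' @param S total microbial ASV pool size.
#' @param depth_mat,depth_individual reads per mat sample / per individual.
#' @param n_washed,n_unwashed individuals per replicate per host.
#' @param gamma_internal,gamma_external host-filter selection strengths on
#'   the log scale (internal stronger than external by default).
#' @param internal_richness_frac,external_richness_frac fraction of the ASV
#'   pool colonizable internally / externally (0.25 and 0.6: mats carry the
#'   full pool, external communities a filtered majority, guts a narrow
#'   subset).
#' @param phi external mass fraction mixed into unwashed individuals.
#' @param host_read_frac fraction of an individual's reads that are host
#'   amplicons.
#' @param sigma_stream,sigma_mat log-scale SDs of stream and mat-type
#'   effects on mat composition.
#' @param sigma_replicate log-scale SD of replicate-level noise.
#' @param n_controls number of negative-control samples.
#' @param n_low_depth number of extra under-sequenced individuals (depth
#'   below the 100-read discard threshold) included to exercise the filter.
#' @param seed integer seed.
#' @return validated list of parameters (class `SimulationParams`).
#' @export
simulationParams <- function(n_streams = 4, mat_types = 2,
                             replicates_per_mat = 3, hosts = 3, S = 400,
                             depth_mat = 20000, depth_individual = 2000,
                             n_washed = 2, n_unwashed = 2,
                             gamma_internal = 2.0, gamma_external = 0.7,
                             internal_richness_frac = 0.25,
                             external_richness_frac = 0.6,
                             phi = 0.4, host_read_frac = 0.3,
                             sigma_stream = 0.8, sigma_mat = 0.4,
                             sigma_replicate = 0.2,
                             n_controls = 2, n_low_depth = 3, seed = 1) {
  p <- as.list(environment())
  fracs <- c(internal_richness_frac = p$internal_richness_frac,
             external_richness_frac = p$external_richness_frac,
             phi = p$phi, host_read_frac = p$host_read_frac)
  if (any(fracs < 0 | fracs > 1))
    .stopf("fraction parameter out of [0,1]: %s",
           paste(names(fracs)[fracs < 0 | fracs > 1], collapse = ", "))
  if (any(c(p$gamma_internal, p$gamma_external, p$sigma_stream, p$sigma_mat,
            p$sigma_replicate) < 0))
    .stopf("strength/sd parameters must be >= 0")
  if (p$n_streams < 1 || p$mat_types < 1 || p$mat_types > 2 ||
      p$replicates_per_mat < 1 || p$hosts < 1 || p$hosts > 3 || p$S < 2)
    .stopf("invalid design dimensions")
  structure(p, class = "SimulationParams")
}

# softmax of a log-abundance vector
.softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# fabricate a lineage string pool for S microbial ASVs
.makeTaxonomy <- function(asv_ids, host_asvs, hosts) {
  S <- length(asv_ids)
  phy <- sample(.PHYLUM_POOL, S, replace = TRUE)
  gen <- sample(.GENUS_POOL, S, replace = TRUE)
  tax <- data.frame(
    asv_id = asv_ids,
    domain = "Eukaryota", phylum = phy,
    class = paste0(phy, "_cl"), order = paste0(phy, "_or"),
    family = paste0(gen, "aceae"), genus = gen,
    percent_identity = round(stats::runif(S, 96, 100), 1),
    query_coverage = round(stats::runif(S, 92, 100), 1),
    stringsAsFactors = FALSE)
  # a few ASVs with non-target or missing domain to exercise the filter
  n_off <- max(1L, round(0.02 * S))
  off <- sample(S, 2L * n_off)
  tax$domain[off[seq_len(n_off)]] <- "Bacteria"
  tax$domain[off[(n_off + 1L):(2L * n_off)]] <- ""
  host_lineage <- data.frame(
    asv_id = host_asvs,
    domain = "Eukaryota", phylum = "Metazoa_ph", class = "Metazoa_cl",
    order = "Metazoa_or",
    family = paste0(hosts, "_fam"), genus = hosts,
    # one host ASV per host is confidently assigned; quality drawn high
    percent_identity = round(stats::runif(length(hosts), 97, 100), 1),
    query_coverage = round(stats::runif(length(hosts), 95, 100), 1),
    stringsAsFactors = FALSE)
  rbind(tax, host_lineage)
}

#' Generate a complete synthetic study
#'
#' Builds, from one seed: (1) a pool of `S` ASVs with log-normal base
#' abundances, a random bifurcating tree with exponential branch lengths
#' over all tips, and fabricated taxonomy; (2) a mat composition per
#' (stream, mat type, replicate) as a softmax of base log-abundance plus
#' Normal stream, mat-type and replicate effects; (3) per-host internal and
#' external ground-truth compositions as the mat composition reweighted by
#' `exp(gamma * w)` for host-filter weights `w ~ N(0, 1)`, with support
#' truncated to the highest-weight fraction of the pool
#' (`internal_richness_frac` and `external_richness_frac`); (4) multinomial
#' reads: washed individuals from the internal composition plus host reads,
#' unwashed individuals from the mixture `(1 - phi) * internal +
#' phi * external` plus host reads, mat samples from the mat composition;
#' (5) sparse low-count negative controls and a few under-sequenced
#' individuals. Same seed, byte-identical outputs.
#'
#' @param params a [simulationParams()] list.
#' @return list with `table` ([AsvExperiment-class] in counts mode,
#'   marker 18S), `taxonomy`, `metadata`, `tree` (`ape::phylo`), and `truth`
#'   (ground-truth compositions and host-filter weights).
#' @export
generateStudy <- function(params = simulationParams()) {
  stopifnot(inherits(params, "SimulationParams"))
  p <- params
  withSeed(p$seed, function() {
    streams <- .DEFAULT_STREAMS[seq_len(p$n_streams)]
    if (p$n_streams > length(.DEFAULT_STREAMS))
      streams <- c(.DEFAULT_STREAMS,
                   sprintf("Stream%d", seq_len(p$n_streams - 4)))
    mat_types <- .MAT_TYPES[seq_len(p$mat_types)]
    hosts <- .DEFAULT_HOSTS[seq_len(p$hosts)]
    asv_ids <- sprintf("asv%04d", seq_len(p$S))
    host_asvs <- paste0("host_", hosts)
    all_ids <- c(asv_ids, host_asvs)

    base_log <- stats::rnorm(p$S, 0, 1)
    tree <- ape::rtree(length(all_ids), tip.label = sample(all_ids),
                       br = stats::rexp)
    taxonomy <- .makeTaxonomy(asv_ids, host_asvs, hosts)

    stream_eff <- matrix(stats::rnorm(length(streams) * p$S, 0, p$sigma_stream),
                         length(streams), p$S, dimnames = list(streams, NULL))
    mat_eff <- matrix(stats::rnorm(length(mat_types) * p$S, 0, p$sigma_mat),
                      length(mat_types), p$S, dimnames = list(mat_types, NULL))
    w <- matrix(stats::rnorm(length(hosts) * p$S, 0, 1), length(hosts), p$S,
                dimnames = list(hosts, NULL))
    k_int <- max(1L, round(p$internal_richness_frac * p$S))
    k_ext <- max(1L, round(p$external_richness_frac * p$S))
    support <- lapply(hosts, function(h) {
      o <- order(w[h, ], decreasing = TRUE)
      list(internal = o[seq_len(k_int)], external = o[seq_len(k_ext)])
    })
    names(support) <- hosts

    design <- expand.grid(stream = streams, mat_type = mat_types,
                          replicate = seq_len(p$replicates_per_mat),
                          stringsAsFactors = FALSE)

    truth <- list(mat = list(), internal = list(), external = list(),
                  host_weights = w)
    counts <- list(); meta <- list()
    addSample <- function(id, reads, class, host, wash, stream, mat_type,
                          replicate) {
      counts[[id]] <<- reads
      meta[[id]] <<- data.frame(sample_id = id, sample_class = class,
                                host = host, wash_status = wash,
                                stream = stream, mat_type = mat_type,
                                replicate = replicate, marker = "18S",
                                stringsAsFactors = FALSE)
    }
    drawIndividual <- function(comp, depth, host_asv) {
      n_host <- round(depth * p$host_read_frac)
      reads <- stats::setNames(numeric(length(all_ids)), all_ids)
      reads[asv_ids] <- stats::rmultinom(1, depth - n_host, comp)[, 1]
      reads[host_asv] <- n_host
      reads
    }

    for (r in seq_len(nrow(design))) {
      st <- design$stream[r]; mt <- design$mat_type[r]
      rep_i <- design$replicate[r]
      key <- sprintf("%s|%s|%d", st, mt, rep_i)
      rep_noise <- stats::rnorm(p$S, 0, p$sigma_replicate)
      mat_comp <- .softmax(base_log + stream_eff[st, ] + mat_eff[mt, ] +
                           rep_noise)
      truth$mat[[key]] <- mat_comp
      mat_id <- sprintf("mat.%s.%s.r%d", st, mt, rep_i)
      mat_reads <- stats::setNames(numeric(length(all_ids)), all_ids)
      mat_reads[asv_ids] <- stats::rmultinom(1, p$depth_mat, mat_comp)[, 1]
      addSample(mat_id, mat_reads, "mat", "none", "not_applicable", st, mt,
                rep_i)

      for (h in hosts) {
        int_comp <- numeric(p$S)
        sup <- support[[h]]$internal
        int_comp[sup] <- mat_comp[sup] * exp(p$gamma_internal * w[h, sup])
        int_comp <- int_comp / sum(int_comp)
        ext_comp <- numeric(p$S)
        sup <- support[[h]]$external
        ext_comp[sup] <- mat_comp[sup] * exp(p$gamma_external * w[h, sup])
        ext_comp <- ext_comp / sum(ext_comp)
        hkey <- sprintf("%s|%s", h, key)
        truth$internal[[hkey]] <- int_comp
        truth$external[[hkey]] <- ext_comp
        mix <- (1 - p$phi) * int_comp + p$phi * ext_comp
        for (i in seq_len(p$n_washed))
          addSample(sprintf("ind.%s.%s.%s.r%d.w%d", h, st, mt, rep_i, i),
                    drawIndividual(int_comp, p$depth_individual,
                                   paste0("host_", h)),
                    "individual", h, "washed", st, mt, rep_i)
        for (i in seq_len(p$n_unwashed))
          addSample(sprintf("ind.%s.%s.%s.r%d.u%d", h, st, mt, rep_i, i),
                    drawIndividual(mix, p$depth_individual,
                                   paste0("host_", h)),
                    "individual", h, "unwashed", st, mt, rep_i)
      }
    }

    # sparse low-count contamination in negative controls
    for (c_i in seq_len(p$n_controls)) {
      reads <- stats::setNames(numeric(length(all_ids)), all_ids)
      n_contam <- min(5L, p$S)
      contam <- sample(p$S, n_contam)
      reads[asv_ids[contam]] <- sample(1:5, n_contam, replace = TRUE)
      addSample(sprintf("control.%d", c_i), reads, "control", "none",
                "not_applicable", streams[1], mat_types[1], 1L)
    }
    # under-sequenced individuals that the depth filter should discard
    for (l_i in seq_len(p$n_low_depth)) {
      h <- hosts[1 + (l_i - 1) %% length(hosts)]
      comp <- truth$internal[[sprintf("%s|%s|%s|%d", h, streams[1],
                                      mat_types[1], 1L)]]
      addSample(sprintf("ind.lowdepth.%d", l_i),
                drawIndividual(comp, 50, paste0("host_", h)),
                "individual", h, "washed", streams[1], mat_types[1], 1L)
    }

    m <- do.call(cbind, counts)
    rownames(m) <- all_ids
    metadata_df <- do.call(rbind, meta)
    rownames(metadata_df) <- NULL
    table <- AsvExperiment(m, mode = "counts", marker = "18S",
                           colData = DataFrame(metadata_df,
                                               row.names = metadata_df$sample_id))
    truth$asv_ids <- asv_ids
    list(table = table, taxonomy = taxonomy,
         metadata = validateSampleMetadata(metadata_df), tree = tree,
         truth = truth, params = p)
  })
}

#' Summarize the target orderings encoded in the ground truth
#'
#' Reports, directly from the generator's ground-truth compositions: the
#' per-replicate richness ordering mat vs external vs internal; and whether
#' host identity dominates internal compositions while the environment
#' dominates external ones, measured as mean between-host vs between-stream
#' Bray-Curtis distance on the truth compositions.
#'
#' @param truth the `truth` element of [generateStudy()]'s return value.
#' @param params the matching [simulationParams()].
#' @return list with `richness_ordering_all_replicates` (logical),
#'   `richness` (data.frame per replicate key), and per-microbiome
#'   between-host/between-stream mean distances.
#' @export
expectedPatterns <- function(truth, params) {
  rich <- function(v) sum(v > 0)
  keys <- names(truth$mat)
  rows <- lapply(keys, function(k) {
    hkeys <- grep(paste0("\\|", gsub("\\|", "\\\\|", k), "$"),
                  names(truth$internal), value = TRUE)
    data.frame(key = k, mat = rich(truth$mat[[k]]),
               external = max(vapply(truth$external[hkeys], rich, 0L)),
               internal = max(vapply(truth$internal[hkeys], rich, 0L)))
  })
  rich_df <- do.call(rbind, rows)
  ordering <- all(rich_df$mat > rich_df$external &
                  rich_df$external > rich_df$internal)

  contrast <- function(comps) {
    ids <- names(comps)
    host <- sub("\\|.*", "", ids)
    stream <- vapply(strsplit(ids, "|", fixed = TRUE), `[[`, "", 2)
    m <- do.call(cbind, comps)
    d <- brayCurtis(m)
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    same_h <- host[pairs[, 1]] == host[pairs[, 2]]
    same_s <- stream[pairs[, 1]] == stream[pairs[, 2]]
    dv <- d[upper.tri(d)]
    c(between_host = mean(dv[!same_h & same_s]),
      between_stream = mean(dv[same_h & !same_s]))
  }
  int_c <- contrast(truth$internal)
  ext_c <- contrast(truth$external)
  list(richness_ordering_all_replicates = ordering, richness = rich_df,
       internal_between_host = int_c[["between_host"]],
       internal_between_stream = int_c[["between_stream"]],
       external_between_host = ext_c[["between_host"]],
       external_between_stream = ext_c[["between_stream"]],
       host_dominates_internal = int_c[["between_host"]] >
         int_c[["between_stream"]],
       environment_dominates_external = ext_c[["between_stream"]] >=
         ext_c[["between_host"]])
  }
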