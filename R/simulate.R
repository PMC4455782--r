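# Synthetic multi-species communities and Hi-C pair libraries.
#
# The generator reproduces the statistical structure the binning method
# relies on: read pairs overwhelmingly join loci of the same cell, cis
# contact frequency decays as a power law of genomic separation, species
# contribute pairs in proportion to abundance x lysis efficiency x genome
# size, and informative read ends sit near restriction sites.

#' Configure a synthetic community and Hi-C library
#'
#' @param species Data frame with one row per species: `label`,
#'   `genome_length` (bp); optional `n_chromosomes` (default 1),
#'   `plasmid_length` (bp, default 0), `abundance` (default 1),
#'   `lysis_efficiency` (default 1).
#' @param shared_segments Optional data frame of exact-copy shared regions:
#'   `species_a`, `species_b`, `segment_length` (bp). The copied sequence
#'   lives in both genomes, so contigs overlapping it carry both species
#'   labels in the truth table.
#' @param enzyme_motif Restriction motif; default HindIII `"AAGCTT"`.
#' @param contig_mode `list(mode = "fixed_bins", bin = 10000)` to split
#'   replicons into fixed-size bins, or
#'   `list(mode = "variable", meanlog =, sdlog =)` for lognormal contig
#'   lengths (minimum 1 kb).
#' @param n_pairs Number of Hi-C read pairs to emit.
#' @param cis_fraction Probability that a same-cell pair is intra-replicon
#'   with power-law separation; default 0.9.
#' @param cis_decay_exponent Exponent of the separation distribution
#'   `P(s) ~ s^-a` on `[1 kb, replicon length]`; default 1.
#' @param noise_fraction Probability that a pair joins two different
#'   species (spurious inter-cellular ligation); default 0.
#' @param site_window Endpoints are placed within a uniform offset of at
#'   most this many bp from the nearest restriction site, so the proximity
#'   filter's behaviour is controllable; default 500.
#' @param planted_site_spacing If > 0, motif occurrences are additionally
#'   planted about every this many bp to guarantee filterable reads;
#'   0 (default) relies on motif occurrences arising naturally in the
#'   uniform background (expected spacing `4^|motif|` bp).
#' @param site_placement_jitter Uniform perturbation (bp) applied to each
#'   planted site position.
#' @param seed Integer seed; genomes and the pair library are fully
#'   reproducible from it.
#' @return A validated `sim_config` object.
#' @export
sim_config <- function(species,
                       shared_segments = NULL,
                       enzyme_motif = "AAGCTT",
                       contig_mode = list(mode = "fixed_bins", bin = 10000),
                       n_pairs = 100000,
                       cis_fraction = 0.9,
                       cis_decay_exponent = 1,
                       noise_fraction = 0,
                       site_window = 500,
                       planted_site_spacing = 0,
                       site_placement_jitter = 0,
                       seed = 1L) {
  species <- as_tibble(species)
  if (!"n_chromosomes" %in% names(species)) species$n_chromosomes <- 1L
  if (!"plasmid_length" %in% names(species)) species$plasmid_length <- 0L
  if (!"abundance" %in% names(species)) species$abundance <- 1
  if (!"lysis_efficiency" %in% names(species)) species$lysis_efficiency <- 1

  problems <- character()
  need <- c("label", "genome_length")
  if (!all(need %in% names(species))) {
    problems <- c(problems, paste0("species: columns ",
                                   paste(setdiff(need, names(species)), collapse = ", "),
                                   " missing"))
  } else {
    if (anyDuplicated(species$label)) problems <- c(problems, "species$label: duplicates")
    if (any(species$abundance <= 0)) problems <- c(problems, "species$abundance: must be > 0")
    if (any(species$lysis_efficiency <= 0)) {
      problems <- c(problems, "species$lysis_efficiency: must be > 0")
    }
    if (any(species$genome_length < species$n_chromosomes * 1000)) {
      problems <- c(problems, "species$genome_length: must be >= n_chromosomes * 1 kb")
    }
  }
  if (cis_fraction < 0 || cis_fraction > 1) problems <- c(problems, "cis_fraction: not in [0, 1]")
  if (noise_fraction < 0 || noise_fraction > 1) {
    problems <- c(problems, "noise_fraction: not in [0, 1]")
  }
  if (site_window < 0) problems <- c(problems, "site_window: must be >= 0")
  if (n_pairs < 0) problems <- c(problems, "n_pairs: must be >= 0")
  if (!contig_mode$mode %in% c("fixed_bins", "variable")) {
    problems <- c(problems, "contig_mode$mode: must be 'fixed_bins' or 'variable'")
  }
  if (!is.null(shared_segments)) {
    shared_segments <- as_tibble(shared_segments)
    if (!all(c("species_a", "species_b", "segment_length") %in% names(shared_segments))) {
      problems <- c(problems, "shared_segments: need species_a, species_b, segment_length")
    }
  }
  if (length(problems) > 0L) {
    abort(paste0("invalid simulation config:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  structure(
    list(species = species, shared_segments = shared_segments,
         enzyme_motif = check_motif(enzyme_motif), contig_mode = contig_mode,
         n_pairs = as.integer(n_pairs), cis_fraction = cis_fraction,
         cis_decay_exponent = cis_decay_exponent,
         noise_fraction = noise_fraction, site_window = site_window,
         planted_site_spacing = planted_site_spacing,
         site_placement_jitter = site_placement_jitter,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation config from YAML
#'
#' Flat YAML with a `species:` list of per-species maps and any of the
#' scalar fields of [sim_config()] (plus `contig_mode: {mode:, bin:}` and a
#' `shared_segments:` list).
#'
#' @param path YAML path.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$species)) abort("config must declare a 'species' list")
  species <- dplyr::bind_rows(purrr::map(y$species, as_tibble))
  shared <- if (!is.null(y$shared_segments)) {
    dplyr::bind_rows(purrr::map(y$shared_segments, as_tibble))
  } else NULL
  args <- y[setdiff(names(y), c("species", "shared_segments"))]
  if (!is.null(args$contig_mode)) args$contig_mode <- as.list(args$contig_mode)
  do.call(sim_config, c(list(species = species, shared_segments = shared), args))
}

random_dna <- function(n) {
  intToUtf8(c(65L, 67L, 71L, 84L)[sample.int(4L, n, replace = TRUE)])
}

plant_motif <- function(seq, motif, spacing, jitter) {
  L <- nchar(seq)
  ml <- nchar(motif)
  if (spacing <= 0 || L <= ml) return(seq)
  pos <- seq.int(spacing, L - ml, by = spacing)
  if (jitter > 0) {
    pos <- pos + round(stats::runif(length(pos), -jitter, jitter))
    pos <- pmin(pmax(pos, 0L), L - ml)
  }
  for (p in pos) substr(seq, p + 1L, p + ml) <- motif
  seq
}

# Inverse-CDF sampler for a continuous power law P(s) ~ s^-alpha on
# [smin, smax].
sample_powerlaw <- function(n, smin, smax, alpha) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    smin * (smax / smin)^u
  } else {
    (smin^(1 - alpha) + u * (smax^(1 - alpha) - smin^(1 - alpha)))^(1 / (1 - alpha))
  }
}

#' Simulate the genomes, contigs and truth table of a community
#'
#' Generates i.i.d. uniform A/C/G/T replicon sequences per species (motif
#' occurrences arise naturally; optionally extra sites are planted),
#' applies exact-copy shared segments, and cuts replicons into contigs
#' according to the config's contig mode. Contigs overlapping a shared
#' segment — on the source or destination genome — carry both species
#' labels in the truth table.
#'
#' @param config A `sim_config`.
#' @return A `sim_community`: `$replicons` (tibble `species`, `replicon`,
#'   `length`, `is_plasmid`, `seq`, `sites`), `$contigs` (contig tibble
#'   with `sites`/`site_count`, plus `species`, `replicon`, `start`),
#'   `$truth` (tibble `contig_id`, `species`), `$config`.
#' @export
simulate_genomes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  motif <- config$enzyme_motif

  reps <- purrr::pmap_dfr(config$species, function(label, genome_length,
                                                   n_chromosomes, plasmid_length,
                                                   abundance, lysis_efficiency) {
    n_chr <- as.integer(n_chromosomes)
    base <- genome_length %/% n_chr
    lens <- rep(base, n_chr)
    lens[n_chr] <- lens[n_chr] + genome_length - sum(lens)
    out <- tibble(
      species = label,
      replicon = paste0(label, "_chr", seq_len(n_chr)),
      length = lens, is_plasmid = FALSE
    )
    if (plasmid_length > 0) {
      out <- dplyr::bind_rows(out, tibble(
        species = label, replicon = paste0(label, "_p1"),
        length = as.integer(plasmid_length), is_plasmid = TRUE
      ))
    }
    out
  })
  reps$seq <- purrr::map_chr(reps$length, random_dna)
  if (config$planted_site_spacing > 0) {
    reps$seq <- purrr::map_chr(
      reps$seq, plant_motif, motif = motif,
      spacing = config$planted_site_spacing,
      jitter = config$site_placement_jitter
    )
  }

  shared_intervals <- tibble(replicon = character(), start = integer(),
                             end = integer(), partner = character())
  if (!is.null(config$shared_segments)) {
    for (i in seq_len(nrow(config$shared_segments))) {
      seg <- config$shared_segments[i, ]
      src <- which(reps$species == seg$species_a & !reps$is_plasmid)[1L]
      dst <- which(reps$species == seg$species_b & !reps$is_plasmid)[1L]
      if (is.na(src) || is.na(dst)) {
        abort(paste0("shared segment references unknown species: ",
                     seg$species_a, " / ", seg$species_b))
      }
      len <- as.integer(seg$segment_length)
      if (len > reps$length[src] || len > reps$length[dst]) {
        abort("shared segment longer than a participating chromosome")
      }
      s0 <- sample.int(reps$length[src] - len + 1L, 1L) - 1L
      d0 <- sample.int(reps$length[dst] - len + 1L, 1L) - 1L
      piece <- substr(reps$seq[src], s0 + 1L, s0 + len)
      substr(reps$seq[dst], d0 + 1L, d0 + len) <- piece
      shared_intervals <- dplyr::bind_rows(
        shared_intervals,
        tibble(replicon = reps$replicon[src], start = s0, end = s0 + len,
               partner = seg$species_b),
        tibble(replicon = reps$replicon[dst], start = d0, end = d0 + len,
               partner = seg$species_a)
      )
    }
  }
  reps$sites <- purrr::map(reps$seq, find_restriction_sites, motif = motif)

  cm <- config$contig_mode
  contigs <- purrr::pmap_dfr(
    reps[, c("species", "replicon", "length", "seq")],
    function(species, replicon, length, seq) {
      if (cm$mode == "fixed_bins") {
        starts <- seq.int(0L, length - 1L, by = cm$bin)
        lens <- pmin(cm$bin, length - starts)
      } else {
        lens <- integer()
        while (sum(lens) < length) {
          lens <- c(lens, max(1000L, as.integer(round(
            stats::rlnorm(1L, meanlog = cm$meanlog, sdlog = cm$sdlog)
          ))))
        }
        lens[length(lens)] <- length - sum(lens[-length(lens)])
        lens <- lens[lens > 0L]
        starts <- cumsum(c(0L, lens[-length(lens)]))
      }
      tibble(
        id = sprintf("%s_%04d", replicon, seq_along(starts)),
        species = species, replicon = replicon,
        start = as.integer(starts), length = as.integer(lens),
        seq = substring(seq, starts + 1L, starts + lens)
      )
    }
  )
  # contigs tile the replicons, so their site lists are the replicon's
  # sites restricted to offsets where the motif fits wholly inside the bin
  rep_sites <- stats::setNames(reps$sites, reps$replicon)
  ml <- nchar(motif)
  contigs$sites <- purrr::pmap(
    contigs[, c("replicon", "start", "length")],
    function(replicon, start, length) {
      s <- rep_sites[[replicon]]
      as.integer(s[s >= start & s <= start + length - ml] - start)
    }
  )
  contigs$site_count <- lengths(contigs$sites)

  truth <- tibble(contig_id = contigs$id, species = contigs$species)
  if (nrow(shared_intervals) > 0L) {
    extra <- dplyr::inner_join(
      contigs[, c("id", "replicon", "start", "length")],
      shared_intervals, by = "replicon",
      relationship = "many-to-many"
    )
    extra <- extra[extra$start.x < extra$end &
                     extra$start.x + extra$length > extra$start.y, ]
    truth <- dplyr::distinct(dplyr::bind_rows(
      truth, tibble(contig_id = extra$id, species = extra$partner)
    ))
  }
  structure(
    list(config = config, replicons = reps, contigs = contigs,
         truth = dplyr::arrange(truth, .data$contig_id, .data$species),
         shared_intervals = shared_intervals),
    class = "sim_community"
  )
}

#' @export
print.sim_community <- function(x, ...) {
  cat("<sim_community> ", nrow(x$config$species), " species, ",
      nrow(x$replicons), " replicons, ", nrow(x$contigs), " contigs, motif ",
      x$config$enzyme_motif, "\n", sep = "")
  invisible(x)
}

# Snap 0-based positions on one replicon to within `window` bp of the
# nearest restriction site (uniform offset, random side).
snap_to_sites <- function(pos, sites, window, replicon_length) {
  if (length(sites) == 0L || length(pos) == 0L) return(pos)
  i <- findInterval(pos, sites)
  left <- sites[pmax(i, 1L)]
  right <- sites[pmin(i + 1L, length(sites))]
  d_left <- ifelse(i >= 1L, pos - left, Inf)
  d_right <- ifelse(i < length(sites), right - pos, Inf)
  nearest <- ifelse(d_left <= d_right, left, right)
  offset <- round(stats::runif(length(pos), 0, window)) *
    sample(c(-1L, 1L), length(pos), replace = TRUE)
  pmin(pmax(nearest + offset, 0L), replicon_length - 1L)
}

#' Simulate a Hi-C pair library for a community
#'
#' Draws `n_pairs` read pairs. With probability `noise_fraction` a pair
#' joins two different species (each drawn proportionally to
#' abundance x lysis efficiency x genome length); otherwise one species is
#' drawn with the same weights and, with probability `cis_fraction`, the
#' pair is intra-replicon with genomic separation sampled from
#' `P(s) ~ s^-cis_decay_exponent` on `[1 kb, replicon length]`, else the
#' two ends fall uniformly on two different replicons of the same cell.
#' Every endpoint is then moved to within a uniform offset of at most
#' `site_window` bp of its nearest restriction site and mapped from
#' replicon to (contig, offset) coordinates.
#'
#' @param config A `sim_config`.
#' @param community The matching [simulate_genomes()] output.
#' @return A pairs tibble as in [read_pairs()] (0-based positions).
#' @export
simulate_hic <- function(config, community) {
  stopifnot(inherits(config, "sim_config"), inherits(community, "sim_community"))
  set.seed(config$seed + 1L)
  n <- config$n_pairs
  reps <- community$replicons
  sp <- config$species
  if (config$noise_fraction > 0 && nrow(sp) < 2L) {
    abort("noise_fraction > 0 requires at least two species")
  }
  siteless <- setdiff(sp$label, reps$species[lengths(reps$sites) > 0L])
  if (length(siteless) > 0L && config$noise_fraction == 0) {
    warn(paste0("species without restriction sites (their pairs will all be ",
                "filtered): ", paste(siteless, collapse = ", ")))
  }
  genome_len <- stats::setNames(
    purrr::map_dbl(split(reps$length, reps$species), sum)[sp$label], sp$label
  )
  w <- sp$abundance * sp$lysis_efficiency * genome_len
  w <- w / sum(w)

  rep_of_species <- split(seq_len(nrow(reps)), reps$species)
  draw_replicon <- function(species_idx) {
    # replicon drawn proportional to length within the species
    out <- integer(length(species_idx))
    for (si in unique(species_idx)) {
      rows <- rep_of_species[[sp$label[si]]]
      sel <- species_idx == si
      out[sel] <- if (length(rows) == 1L) rows else {
        sample(rows, sum(sel), replace = TRUE, prob = reps$length[rows])
      }
    }
    out
  }

  is_noise <- stats::runif(n) < config$noise_fraction
  s1 <- sample.int(nrow(sp), n, replace = TRUE, prob = w)
  s2 <- s1
  while (any(redo <- is_noise & s2 == s1)) {
    s2[redo] <- sample.int(nrow(sp), sum(redo), replace = TRUE, prob = w)
  }
  is_cis <- !is_noise & stats::runif(n) < config$cis_fraction

  r1 <- integer(n); r2 <- integer(n)
  p1 <- numeric(n); p2 <- numeric(n)

  # cis pairs: same replicon, power-law separation
  ci <- which(is_cis)
  if (length(ci) > 0L) {
    r1[ci] <- draw_replicon(s1[ci])
    r2[ci] <- r1[ci]
    smin <- 1000
    for (r in unique(r1[ci])) {
      sel <- ci[r1[ci] == r]
      L <- reps$length[r]
      if (L < 2 * smin) {
        p1[sel] <- floor(stats::runif(length(sel)) * L)
        p2[sel] <- floor(stats::runif(length(sel)) * L)
      } else {
        s_sep <- floor(sample_powerlaw(length(sel), smin, L - 1, config$cis_decay_exponent))
        a <- floor(stats::runif(length(sel)) * (L - s_sep))
        b <- a + s_sep
        swap <- stats::runif(length(sel)) < 0.5
        p1[sel] <- ifelse(swap, b, a)
        p2[sel] <- ifelse(swap, a, b)
      }
    }
  }

  # trans pairs within a cell: two different replicons when possible
  ti <- which(!is_noise & !is_cis)
  if (length(ti) > 0L) {
    r1[ti] <- draw_replicon(s1[ti])
    r2[ti] <- draw_replicon(s1[ti])
    multi <- lengths(rep_of_species)[sp$label[s1[ti]]] > 1L
    while (any(redo <- multi & r2[ti] == r1[ti])) {
      r2[ti][redo] <- draw_replicon(s1[ti][redo])
    }
    p1[ti] <- floor(stats::runif(length(ti)) * reps$length[r1[ti]])
    p2[ti] <- floor(stats::runif(length(ti)) * reps$length[r2[ti]])
  }

  # noise pairs: independent endpoints in two different species
  ni <- which(is_noise)
  if (length(ni) > 0L) {
    r1[ni] <- draw_replicon(s1[ni])
    r2[ni] <- draw_replicon(s2[ni])
    p1[ni] <- floor(stats::runif(length(ni)) * reps$length[r1[ni]])
    p2[ni] <- floor(stats::runif(length(ni)) * reps$length[r2[ni]])
  }

  # snap endpoints to restriction sites, per replicon
  for (r in unique(c(r1, r2))) {
    sel1 <- r1 == r
    p1[sel1] <- snap_to_sites(p1[sel1], reps$sites[[r]], config$site_window,
                              reps$length[r])
    sel2 <- r2 == r
    p2[sel2] <- snap_to_sites(p2[sel2], reps$sites[[r]], config$site_window,
                              reps$length[r])
  }

  # map replicon coordinates to (contig, offset)
  ctg <- community$contigs
  starts_of <- split(ctg[, c("id", "start")], ctg$replicon)
  contig1 <- character(n); contig2 <- character(n)
  off1 <- integer(n); off2 <- integer(n)
  for (r in unique(c(r1, r2))) {
    tab <- starts_of[[reps$replicon[r]]]
    sel1 <- which(r1 == r)
    if (length(sel1) > 0L) {
      k <- findInterval(p1[sel1], tab$start)
      contig1[sel1] <- tab$id[k]
      off1[sel1] <- as.integer(p1[sel1] - tab$start[k])
    }
    sel2 <- which(r2 == r)
    if (length(sel2) > 0L) {
      k <- findInterval(p2[sel2], tab$start)
      contig2[sel2] <- tab$id[k]
      off2[sel2] <- as.integer(p2[sel2] - tab$start[k])
    }
  }
  strands <- sample(c("+", "-"), 2L * n, replace = TRUE)
  tibble(
    read_id = sprintf("sim_%07d", seq_len(n)),
    contig1 = contig1, pos1 = off1, strand1 = strands[seq_len(n)],
    contig2 = contig2, pos2 = off2, strand2 = strands[n + seq_len(n)]
  )
}

#' Write a simulated community to disk
#'
#' Emits `genomes.fasta` (replicons), `contigs.fasta`, `truth.tsv` and, if
#' `pairs` is given, `library.pairs`.
#'
#' @param community A `sim_community`.
#' @param dir Output directory (created if needed).
#' @param pairs Optional pairs tibble from [simulate_hic()].
#' @return The directory path, invisibly.
#' @export
write_community <- function(community, dir, pairs = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_assembly(
    tibble(id = community$replicons$replicon, seq = community$replicons$seq),
    file.path(dir, "genomes.fasta")
  )
  write_assembly(community$contigs, file.path(dir, "contigs.fasta"))
  write_truth(community$truth, file.path(dir, "truth.tsv"))
  if (!is.null(pairs)) write_pairs(pairs, file.path(dir, "library.pairs"))
  invisible(dir)
}
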