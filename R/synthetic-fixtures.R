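## Deterministic generator of seed networks and RegIN collections with
## controlled cross-RegIN overlap. Ground truth (the exact supporting
## RegIN set of every regulator->target pair and its qualification under
## each direction mode) is recorded constructively while the fixture is
## generated — never by running the linker — so agreement between the two
## is a genuine oracle test.

#' Parameters of the synthetic fixture generator
#'
#' @param nSeedNodes Number of seed nodes.
#' @param nRegins Number of RegINs.
#' @param regulatorsPerRegin Size of the regulator pool each RegIN draws
#'   from (the pool is global, so regulators recur across RegINs).
#' @param interactionsPerRegin Interactions per RegIN, including a fixed
#'   quarter of background interactions touching no seed node.
#' @param overlapFraction Fraction in [0,1] of each RegIN's qualifying
#'   interactions drawn from a pool shared by all RegINs (so those pairs
#'   have support = nRegins); requires nRegins >= 2 when positive.
#' @param directionMix Fraction of qualifying interactions in which the
#'   seed node is the target (a regulator is added); the remainder have
#'   the seed node as regulator (targets are added).
#' @param rngSeed Integer seed; the same seed gives byte-identical output.
#' @return A [FixtureSpec-class].
#' @export
fixtureSpec <- function(nSeedNodes = 10L, nRegins = 3L,
                        regulatorsPerRegin = 8L,
                        interactionsPerRegin = 40L,
                        overlapFraction = 0.2, directionMix = 0.5,
                        rngSeed = 1L) {
  new("FixtureSpec", nSeedNodes = as.integer(nSeedNodes),
      nRegins = as.integer(nRegins),
      regulatorsPerRegin = as.integer(regulatorsPerRegin),
      interactionsPerRegin = as.integer(interactionsPerRegin),
      overlapFraction = as.numeric(overlapFraction),
      directionMix = as.numeric(directionMix),
      rngSeed = as.integer(rngSeed))
}

# Identifier sets of the synthetic molecule universe: every molecule has a
# primary id in the fake system "sysP" plus aliases in "sysA"/"sysB".
.FIXTURE_PRIORITY <- c("sysP", "sysA", "sysB")

.molIds <- function(prefix, i, systems = c("sysP", "sysA", "sysB")) {
  vals <- c(sysP = sprintf("%sP%04d", prefix, i),
            sysA = sprintf("%sA%04d", prefix, i),
            sysB = sprintf("%sB%04d", prefix, i))
  vals[systems]
}

.fixtureReginNode <- function(ids, label, biotype) {
  list(nodeId = unname(ids[["sysP"]]), label = label, biotype = biotype,
       identifiers = ids)
}

#' Generate a synthetic seed network and RegIN collection
#'
#' See [fixtureSpec()] for the knobs. The generator emulates the shape of
#' real RegIN collections — several identifier systems per node, regulators
#' recurring across sources, a controlled fraction of interactions present
#' in every source, and background interactions that touch no seed node —
#' while making no claim to realistic interaction-count distributions.
#'
#' @param spec A [FixtureSpec-class].
#' @param dir Optional directory; when given, \code{seed.xgmml}, one
#'   \code{reginNN.xgmml} per RegIN and \code{groundtruth.json} are written
#'   there (created if needed).
#' @return A list with \code{seed} ([SeedNetwork-class]), \code{regins}
#'   (list of [RegIN-class]), \code{groundTruth} (data.frame: \code{source}
#'   and \code{target} in extended-graph node ids, list-column
#'   \code{regins}, logicals \code{qualifiesTargets},
#'   \code{qualifiesRegulators}, \code{qualifiesBoth}) and \code{priority}
#'   (the identifier-system priority to use when extending).
#' @export
generateFixture <- function(spec, dir = NULL) {
  stopifnot(is(spec, "FixtureSpec"))
  validObject(spec)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec@rngSeed)

  n <- spec@nSeedNodes
  seedIdsList <- lapply(seq_len(n), function(i) .molIds("G", i))
  # each seed node exposes its identifier in one randomly chosen system
  seedSystem <- if (n) sample(c("sysP", "sysA"), n, replace = TRUE) else
    character()
  seedNodeIds <- sprintf("S%03d", seq_len(n))
  sn <- data.frame(nodeId = seedNodeIds, stringsAsFactors = FALSE)
  sn$attrs <- I(lapply(seq_len(n), function(i) {
    list(identifier = unname(seedIdsList[[i]][[seedSystem[i]]]),
         label = sprintf("gene-%03d", i))
  }))
  nSeedEdges <- if (n >= 2L) n %/% 2L else 0L
  se <- if (nSeedEdges) {
    ends <- replicate(nSeedEdges, sample(n, 2L))
    data.frame(source = seedNodeIds[ends[1L, ]],
               target = seedNodeIds[ends[2L, ]],
               stringsAsFactors = FALSE)
  } else {
    data.frame(source = character(), target = character(),
               stringsAsFactors = FALSE)
  }
  se$attrs <- I(rep(list(list(interaction = "pp")), nrow(se)))
  seed <- seedNetwork(sn, edges = se, idAttribute = "identifier")

  nBackground <- spec@interactionsPerRegin %/% 4L
  nQual <- spec@interactionsPerRegin - nBackground
  nShared <- if (spec@nRegins >= 2L) round(spec@overlapFraction * nQual) else 0L
  nUnique <- nQual - nShared
  nReg <- spec@regulatorsPerRegin
  regIds <- function(i) .molIds("R", i)
  # pair registry: non-shared qualifying interactions must be globally
  # unique, or a pair's support set would differ from its construction
  usedPairs <- new.env(hash = TRUE, parent = emptyenv())
  extraReg <- nReg

  # an interaction is a list(srcKind, srcIdx, tgtKind, tgtIdx) over the
  # molecule universe; kinds: seed / regulator / gene (added target) /
  # bgGene (background target)
  geneCounter <- 0L
  newGene <- function() {
    geneCounter <<- geneCounter + 1L
    geneCounter
  }
  makeQualifying <- function() {
    if (n == 0L) return(NULL)
    if (nReg > 0L && stats::runif(1L) < spec@directionMix) {
      # seed node is the target: regulator -> seed; the pair must be new
      for (try in 1:50) {
        x <- list(srcKind = "regulator", srcIdx = sample.int(nReg, 1L),
                  tgtKind = "seed", tgtIdx = sample.int(n, 1L))
        k <- paste(x$srcIdx, x$tgtIdx)
        if (is.null(usedPairs[[k]])) {
          usedPairs[[k]] <- TRUE
          return(x)
        }
      }
      # pool exhausted: a fresh regulator guarantees a fresh pair
      extraReg <<- extraReg + 1L
      x <- list(srcKind = "regulator", srcIdx = extraReg,
                tgtKind = "seed", tgtIdx = sample.int(n, 1L))
      usedPairs[[paste(x$srcIdx, x$tgtIdx)]] <- TRUE
      x
    } else {
      # seed node is the regulator: seed -> new target gene (always new)
      list(srcKind = "seed", srcIdx = sample.int(n, 1L),
           tgtKind = "gene", tgtIdx = newGene())
    }
  }
  makeBackground <- function() {
    list(srcKind = "regulator",
         srcIdx = if (nReg) sample.int(nReg, 1L) else 1L,
         tgtKind = "bgGene", tgtIdx = newGene())
  }

  shared <- Filter(Negate(is.null), replicate(nShared, makeQualifying(),
                                              simplify = FALSE))
  reginIa <- lapply(seq_len(spec@nRegins), function(r) {
    uniq <- Filter(Negate(is.null), replicate(nUnique, makeQualifying(),
                                              simplify = FALSE))
    bg <- replicate(nBackground, makeBackground(), simplify = FALSE)
    c(shared, uniq, bg)
  })

  ## materialise RegINs and record ground truth constructively
  molKey <- function(kind, idx) {
    switch(kind,
      seed = seedNodeIds[idx],                      # attaches to seed node
      regulator = paste0("added:", regIds(idx)[["sysP"]]),
      gene = paste0("added:", sprintf("TP%04d", idx)),
      bgGene = paste0("added:", sprintf("BP%04d", idx)))
  }
  gtRegins <- list()
  gtKind <- list()
  rnames <- sprintf("regin%02d", seq_len(spec@nRegins))
  regins <- vector("list", spec@nRegins)
  for (r in seq_len(spec@nRegins)) {
    nodes <- list()
    addNode <- function(kind, idx) {
      key <- paste(kind, idx)
      if (!is.null(nodes[[key]])) return(nodes[[key]]$nodeId)
      node <- switch(kind,
        seed = .fixtureReginNode(seedIdsList[[idx]],
                                 sprintf("gene-%03d", idx), "gene"),
        regulator = {
          # regulators carry the primary system plus a random alias subset
          sys <- c("sysP", sample(c("sysA", "sysB"),
                                  sample(0:2, 1L)))
          .fixtureReginNode(regIds(idx)[unique(sys)],
                            sprintf("mir-%04d", idx), "microRNA")
        },
        gene = .fixtureReginNode(
          c(sysP = sprintf("TP%04d", idx), sysA = sprintf("TA%04d", idx)),
          sprintf("target-%04d", idx), "gene"),
        bgGene = .fixtureReginNode(
          c(sysP = sprintf("BP%04d", idx)),
          sprintf("bg-%04d", idx), "gene"))
      nodes[[key]] <<- node
      node$nodeId
    }
    ia <- list()
    for (x in reginIa[[r]]) {
      sId <- addNode(x$srcKind, x$srcIdx)
      tId <- addNode(x$tgtKind, x$tgtIdx)
      ia[[length(ia) + 1L]] <- list(
        sourceId = sId, targetId = tId,
        evidence = list(pmid = sprintf("%07d", sample.int(9999999, 1L))))
      # constructive bookkeeping, independent of the linker
      pk <- paste(molKey(x$srcKind, x$srcIdx),
                  molKey(x$tgtKind, x$tgtIdx), sep = "\r")
      gtRegins[[pk]] <- unique(c(gtRegins[[pk]], rnames[r]))
      gtKind[[pk]] <- if (x$srcKind == "seed") "seedIsRegulator"
      else if (x$tgtKind == "seed") "seedIsTarget" else "background"
    }
    nodeDf <- data.frame(
      nodeId = vapply(nodes, `[[`, "", "nodeId"),
      label = vapply(nodes, `[[`, "", "label"),
      biotype = vapply(nodes, `[[`, "", "biotype"),
      stringsAsFactors = FALSE)
    nodeDf$identifiers <- I(lapply(nodes, `[[`, "identifiers"))
    nodeDf$extra <- I(rep(list(character()), nrow(nodeDf)))
    iaDf <- data.frame(
      sourceId = vapply(ia, `[[`, "", "sourceId"),
      targetId = vapply(ia, `[[`, "", "targetId"),
      stringsAsFactors = FALSE)
    iaDf$interactionType <- rep(
      if (r %% 2L) "predicted MTI" else "validated MTI", nrow(iaDf))
    iaDf$evidence <- I(lapply(ia, `[[`, "evidence"))
    regins[[r]] <- regIN(
      rnames[r], nodeDf, iaDf,
      database = sprintf("synthDB%02d", r), version = "1.0",
      organism = "synthetic",
      interactionType = if (r %% 2L) "predicted MTI" else "validated MTI")
  }

  pairKeys <- names(gtRegins)
  parts <- strsplit(pairKeys, "\r", fixed = TRUE)
  gt <- data.frame(
    source = vapply(parts, `[`, "", 1L),
    target = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE)
  gt$regins <- I(lapply(pairKeys, function(k) sort(gtRegins[[k]])))
  kind <- vapply(pairKeys, function(k) gtKind[[k]], "")
  gt$qualifiesTargets <- kind == "seedIsRegulator"
  gt$qualifiesRegulators <- kind == "seedIsTarget"
  gt$qualifiesBoth <- kind != "background"
  rownames(gt) <- NULL

  out <- list(seed = seed, regins = regins, groundTruth = gt,
              priority = .FIXTURE_PRIORITY)
  if (!is.null(dir)) {
    # RegINs go into their own subdirectory so directory discovery by
    # .xgmml extension does not pick up the seed file
    reginDir <- file.path(dir, "regins")
    if (!dir.exists(reginDir)) dir.create(reginDir, recursive = TRUE)
    seedToXgmml(seed, file.path(dir, "seed.xgmml"))
    for (r in seq_along(regins)) {
      reginToXgmml(regins[[r]],
                   file.path(reginDir, paste0(rnames[r], ".xgmml")))
    }
    gtJson <- list(
      priority = .FIXTURE_PRIORITY,
      pairs = lapply(seq_len(nrow(gt)), function(i) {
        list(source = gt$source[i], target = gt$target[i],
             regins = gt$regins[[i]],
             qualifiesTargets = gt$qualifiesTargets[i],
             qualifiesRegulators = gt$qualifiesRegulators[i],
             qualifiesBoth = gt$qualifiesBoth[i])
      }))
    jsonlite::write_json(gtJson, file.path(dir, "groundtruth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' A fixed workflow-shaped toy fixture
#'
#' Four seed miRNA nodes (synthetic miRBase-style accessions) and four
#' miRNA-target RegINs: two large "predicted" sources and two small
#' "validated" ones, mimicking the shape of a typical four-source MTI
#' integration at desk scale. The designed ground truth: extending with
#' direction "targets" adds (40, 28, 6, 3) interactions for
#' (predictedA, predictedB, validatedA, validatedB); hiding the two
#' predicted RegINs leaves 9 visible added edges; exactly 5 regulator ->
#' target pairs are supported by two or more RegINs, so the overlap
#' threshold 2 keeps exactly those 5 pairs. All identifiers and counts are
#' synthetic.
#'
#' @return A list with \code{seed}, \code{regins} (4 RegINs),
#'   \code{groundTruth} (as [generateFixture()]) and \code{priority}.
#' @export
figure1Toy <- function() {
  mirAcc <- sprintf("SYN-MIMAT-%04d", 1:4)
  mirId <- sprintf("syn-miR-%d", 1:4)
  seedIds <- sprintf("M%d", 1:4)
  sn <- data.frame(nodeId = seedIds, stringsAsFactors = FALSE)
  sn$attrs <- I(lapply(1:4, function(i) {
    list(identifier = mirAcc[i], label = mirId[i])
  }))
  seed <- seedNetwork(sn, idAttribute = "identifier")

  tgtId <- function(i) sprintf("SYNG%03d", i)
  # shared pairs: (miRNA index, target index, supporting RegIN indices)
  sharedPairs <- list(
    list(m = 1L, t = 1L, regins = c(1L, 2L)),
    list(m = 1L, t = 2L, regins = c(1L, 3L)),
    list(m = 2L, t = 3L, regins = c(2L, 4L)),
    list(m = 3L, t = 4L, regins = c(3L, 4L)),
    list(m = 4L, t = 5L, regins = c(1L, 2L, 3L)))
  rnames <- c("predictedA", "predictedB", "validatedA", "validatedB")
  rtypes <- c("predicted MTI", "predicted MTI", "validated MTI",
              "validated MTI")
  totals <- c(40L, 28L, 6L, 3L)

  perRegin <- lapply(1:4, function(r) {
    lapply(Filter(function(p) r %in% p$regins, sharedPairs),
           function(p) c(p$m, p$t))
  })
  nextTarget <- length(sharedPairs)
  for (r in 1:4) {
    mir <- 0L
    while (length(perRegin[[r]]) < totals[r]) {
      nextTarget <- nextTarget + 1L
      mir <- mir %% 4L + 1L
      perRegin[[r]][[length(perRegin[[r]]) + 1L]] <- c(mir, nextTarget)
    }
  }

  gtRegins <- list()
  regins <- vector("list", 4L)
  for (r in 1:4) {
    pairs <- perRegin[[r]]
    mirs <- sort(unique(vapply(pairs, `[`, 0L, 1L)))
    tgts <- sort(unique(vapply(pairs, `[`, 0L, 2L)))
    nodeDf <- data.frame(
      nodeId = c(sprintf("mir%d", mirs), sprintf("t%03d", tgts)),
      label = c(mirId[mirs], tgtId(tgts)),
      biotype = c(rep("microRNA", length(mirs)),
                  rep("gene", length(tgts))),
      stringsAsFactors = FALSE)
    nodeDf$identifiers <- I(c(
      lapply(mirs, function(m) {
        c(`miRBase-accession` = mirAcc[m], `miRBase-id` = mirId[m])
      }),
      lapply(tgts, function(t) {
        c(ensembl = tgtId(t), ncbigene = sprintf("9%05d", t))
      })))
    nodeDf$extra <- I(rep(list(character()), nrow(nodeDf)))
    iaDf <- data.frame(
      sourceId = vapply(pairs, function(p) sprintf("mir%d", p[1L]), ""),
      targetId = vapply(pairs, function(p) sprintf("t%03d", p[2L]), ""),
      interactionType = rtypes[r],
      stringsAsFactors = FALSE)
    iaDf$evidence <- I(lapply(seq_along(pairs), function(i) {
      list(pmid = sprintf("%d%04d", r, i))
    }))
    regins[[r]] <- regIN(rnames[r], nodeDf, iaDf,
                         database = rnames[r], version = "1.0",
                         organism = "synthetic",
                         interactionType = rtypes[r])
    for (p in pairs) {
      pk <- paste(sprintf("M%d", p[1L]),
                  paste0("added:", tgtId(p[2L])), sep = "\r")
      gtRegins[[pk]] <- c(gtRegins[[pk]], rnames[r])
    }
  }
  pairKeys <- names(gtRegins)
  parts <- strsplit(pairKeys, "\r", fixed = TRUE)
  gt <- data.frame(
    source = vapply(parts, `[`, "", 1L),
    target = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE)
  gt$regins <- I(lapply(pairKeys, function(k) sort(gtRegins[[k]])))
  gt$qualifiesTargets <- TRUE
  gt$qualifiesRegulators <- FALSE
  gt$qualifiesBoth <- TRUE
  rownames(gt) <- NULL
  list(seed = seed, regins = regins, groundTruth = gt,
       priority = defaultSystemPriority())
}
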