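test_that("itp reader parses the shipped templates with fragment roles", {
  popg <- templateTopology("popg", "martini22")
  expect_s4_class(popg, "CGTopology")
  expect_equal(moleculeName(popg), "POPG")
  b <- beads(popg)
  expect_equal(nrow(b), 12L)
  expect_equal(sum(b$role == "glycerol"), 2L)
  expect_equal(sum(b$role == "tail"), 8L)
  expect_equal(sum(b$charge), -1)  # the phosphate
  cys <- templateTopology("cys", "martini22")
  expect_equal(beads(cys)$role, c("backbone", "sidechain"))
})

test_that("itp writer/reader round trip preserves every term exactly", {
  for (ff in c("martini22", "martini3")) {
    for (nm in c("popg", "pope", "cys", "palmitoyl")) {
      top <- templateTopology(nm, ff)
      tmp <- tempfile(fileext = ".itp")
      writeITP(top, tmp)
      back <- readITP(tmp)
      expect_identical(moleculeName(back), moleculeName(top))
      expect_equal(beads(back)[, c("name", "type", "charge", "role")],
                   beads(top)[, c("name", "type", "charge", "role")])
      expect_equal(bonds(back)[, c("i", "j", "funct", "length", "k")],
                   bonds(top)[, c("i", "j", "funct", "length", "k")])
      expect_equal(angles(back)[, c("i", "j", "k", "angle", "force")],
                   angles(top)[, c("i", "j", "k", "angle", "force")])
    }
  }
})

test_that("graftDiacyl keeps glycerol + tails and adds one cross bond", {
  cys <- templateTopology("cys")
  popg <- templateTopology("popg")
  di <- graftDiacyl(cys, popg)
  # 2 cysteine beads + 2 glycerol + 8 tail beads
  expect_equal(nrow(beads(di)), 12L)
  expect_equal(sum(beads(di)$role == "headgroup"), 0L)
  expect_equal(sum(beads(di)$role == "phosphate"), 0L)
  # bond bookkeeping: cys bond + new graft bond + retained lipid bonds
  keepBonds <- sum(apply(bonds(popg)[, c("i", "j")], 1, function(p)
    all(beads(popg)$role[p] %in% c("glycerol", "tail"))))
  expect_equal(nrow(bonds(di)), nrow(bonds(cys)) + 1L + keepBonds)
  # the graft joins the side chain to the first glycerol bead
  graft <- bonds(di)[grepl("graft", bonds(di)$comment), ]
  expect_equal(nrow(graft), 1L)
  expect_identical(beads(di)$role[graft$i], "sidechain")
  expect_identical(beads(di)$name[graft$j], "GL1")
  # no dangling indices, connected graph (validity enforces both)
  expect_true(validObject(di))
  # retained template terms preserved verbatim (lengths and constants)
  gl12 <- which(beads(di)$name %in% c("GL1", "GL2"))
  innerBond <- bonds(di)[bonds(di)$i == gl12[1] & bonds(di)$j == gl12[2], ]
  tmplBond <- bonds(popg)[bonds(popg)$i == 3 & bonds(popg)$j == 4, ]
  expect_equal(innerBond$length, tmplBond$length)
  expect_equal(innerBond$k, tmplBond$k)
})

test_that("graftDiacyl validates its inputs and never mutates them", {
  cys <- templateTopology("cys")
  popg <- templateTopology("popg")
  before <- list(beads(cys), bonds(popg))
  stripped <- newCGTopology("XXX", within(beads(popg), role[
    role == "glycerol"] <- "tail"), bonds(popg), angles = angles(popg))
  expect_error(graftDiacyl(cys, stripped), "glycerol")
  d1 <- graftDiacyl(cys, popg)
  d2 <- graftDiacyl(cys, popg)
  expect_identical(d1, d2)  # pure function
  expect_identical(list(beads(cys), bonds(popg)), before)
})

test_that("graftTriacyl bonds a linear palmitoyl to the backbone once", {
  di <- graftDiacyl(templateTopology("cys"), templateTopology("popg"))
  palm <- templateTopology("palmitoyl")
  tri <- graftTriacyl(di, palm)
  expect_equal(nrow(beads(tri)), nrow(beads(di)) + 4L)  # 16 beads
  newBonds <- nrow(bonds(tri)) - nrow(bonds(di)) - nrow(bonds(palm))
  expect_equal(newBonds, 1L)
  expect_true(validObject(tri))  # connectivity holds
  # re-grafting: backbone attachment occupied
  expect_error(graftTriacyl(tri, palm), "occupied")
  # branched fragments are rejected
  branched <- newCGTopology("BR", beads(palm),
                            rbind(bonds(palm),
                                  data.frame(i = 1L, j = 3L, funct = 1L,
                                             length = 0.47, k = 1250,
                                             comment = "")))
  expect_error(graftTriacyl(di, branched), "linear")
})

test_that("grafted charges follow the template arithmetic", {
  for (ff in c("martini22", "martini3")) {
    cys <- templateTopology("cys", ff)
    popg <- templateTopology("popg", ff)
    di <- graftDiacyl(cys, popg)
    keep <- beads(popg)$role %in% c("glycerol", "tail")
    expect_equal(sum(beads(di)$charge),
                 sum(beads(cys)$charge) + sum(beads(popg)$charge[keep]))
    tri <- graftTriacyl(di, templateTopology("palmitoyl", ff))
    # the palmitoyl tail is neutral: triacylation adds no net charge
    expect_equal(sum(beads(tri)$charge), sum(beads(di)$charge))
  }
})

test_that("elastic network matches the brute-force all-pairs oracle", {
  # boundary cases around the 0.7 nm cutoff
  two <- data.frame(chain = "A", resno = 1:2, resname = "ALA", elety = "BB",
                    x = c(0, 6.5), y = 0, z = 0)
  expect_equal(nrow(networkPairs(buildElasticNetwork(two, 0.7))), 1L)
  two$x[2] <- 7.5
  expect_equal(nrow(networkPairs(buildElasticNetwork(two, 0.7))), 0L)
  # random 50-bead cloud vs O(n^2) oracle
  set.seed(99)
  xyz <- matrix(runif(150, 0, 25), 50, 3)
  cloud <- data.frame(chain = "A", resno = 1:50, resname = "ALA",
                      elety = "BB", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  enm <- buildElasticNetwork(cloud, cutoff = 0.7)
  oracle <- oracleENM(xyz / 10, 1:50, 0.7)
  oracle <- oracle[order(oracle$i, oracle$j), ]
  p <- networkPairs(enm)
  expect_equal(p$i, oracle$i)
  expect_equal(p$j, oracle$j)
  expect_equal(p$distance, oracle$distance)
})

test_that("elastic network excludes the disordered tether", {
  toy <- makeToyStructure(seed = 12)
  core <- orientStructure(toy$atoms)
  tri <- assembleState(core, toy$match, "TRI", toy$sequence, orient = FALSE)
  enm <- buildElasticNetwork(tri)
  p <- networkPairs(enm)
  expect_false(any(p$i %in% tri@tetherResnos))
  expect_false(any(p$j %in% tri@tetherResnos))
  expect_gt(nrow(p), 0L)  # the folded core does get restrained
  # an empty network is allowed (fully extended chain)
  line <- data.frame(chain = "A", resno = 1:5, resname = "GLY",
                     elety = "BB", x = 10 * (1:5), y = 0, z = 0)
  expect_equal(nrow(networkPairs(buildElasticNetwork(line, 0.7))), 0L)
  tmp <- tempfile(fileext = ".itp")
  writeElasticNetworkITP(enm, tmp)
  expect_true(any(grepl("bonds", readLines(tmp))))
})
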