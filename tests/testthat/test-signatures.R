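test_that("membership matrix tabulates per-unit calls", {
  genes <- paste0("g", 1:6)
  calls <- list(U1 = toy_de_calls(genes, c("g1", "g2"), c("up", "down")),
                U2 = toy_de_calls(genes, c("g3", "g4"), c("up", "up")))
  mm <- membership_matrix(calls)
  # disjoint calls give block-diagonal membership
  expect_true(all(mm$member[c("g1", "g2"), "U1"]))
  expect_false(any(mm$member[c("g1", "g2"), "U2"]))
  expect_equal(mm$direction["g2", "U1"], "down")
  expect_equal(mm$direction["g3", "U1"], "none")

  # same gene significant in both units
  calls2 <- list(U1 = toy_de_calls(genes, "g1", "up"),
                 U2 = toy_de_calls(genes, "g1", "up"))
  mm2 <- membership_matrix(calls2)
  expect_true(all(mm2$member["g1", ]))
  expect_equal(unname(mm2$direction["g1", ]), c("up", "up"))

  # random calls against brute-force tabulation
  set.seed(7)
  for (rep in 1:5) {
    sig_sets <- lapply(1:3, function(i) sample(genes, sample(1:6, 1)))
    calls3 <- lapply(sig_sets, function(s)
      toy_de_calls(genes, s, sample(c("up", "down"), length(s),
                                    replace = TRUE)))
    names(calls3) <- paste0("U", 1:3)
    mm3 <- membership_matrix(calls3)
    for (u in 1:3) for (g in rownames(mm3$member))
      expect_equal(unname(mm3$member[g, u]), g %in% sig_sets[[u]])
  }
})

test_that("unique/shared partition and upset counts match enumeration", {
  set.seed(11)
  genes <- sprintf("g%02d", 1:20)
  units <- paste0("U", 1:4)
  member <- matrix(runif(80) < 0.4, 20, 4, dimnames = list(genes, units))
  member <- member[rowSums(member) > 0, , drop = FALSE]
  mm <- list(member = member,
             direction = ifelse(member, "up", "none"))
  part <- unique_shared_partition(mm)
  oracle <- brute_partition(member)
  for (u in units) {
    expect_setequal(part$unique[[u]], oracle$unique[[u]])
    expect_setequal(part$shared[[u]], oracle$shared[[u]])
    # conservation: |unique| + |shared| = |DE set| per unit
    expect_equal(length(part$unique[[u]]) + length(part$shared[[u]]),
                 sum(member[, u]))
  }
  expect_equal(nrow(part$upset), 2^4 - 1)
  got <- stats::setNames(part$upset$count, part$upset$pattern)
  expect_equal(got[names(oracle$patterns)], oracle$patterns,
               ignore_attr = TRUE)
  expect_equal(sum(part$upset$count), nrow(member))
})

test_that("BL reconciliation applies union, conflict and hEGFR filters", {
  # hand-built partitions over units A, B
  pfs <- list(unique = list(A = c("u1", "x1", "hEGFR"), B = "u2"),
              shared = list(A = "s1", B = "s1"))
  pss <- list(unique = list(A = "u1", B = character(0)),
              shared = list(A = c("s1", "x1"), B = c("s1", "x1")))
  mmd <- function(genes, unit_genes) NULL  # directions optional
  bl <- reconcile_conditions(pfs, pss)
  # u1 unique in both conditions: kept; u2 unique in FS only: kept (union)
  expect_setequal(signature_genes(bl, "BL_A"), "u1")
  expect_setequal(signature_genes(bl, "BL_B"), "u2")
  # x1 unique in FS but shared in SS: excluded with the conflict reason
  expect_equal(bl$exclusions$reason[bl$exclusions$gene == "x1"],
               "cross-condition-conflict")
  # hEGFR always excluded with its own reason
  expect_equal(bl$exclusions$reason[bl$exclusions$gene == "hEGFR"], "hEGFR")
  # every excluded gene has exactly one logged reason per signature
  expect_false(anyDuplicated(paste(bl$exclusions$gene,
                                   bl$exclusions$signature)) > 0)
  # conservation: candidates = retained + excluded per signature
  for (u in c("A", "B")) {
    cand <- union(pfs$unique[[u]], pss$unique[[u]])
    nsig <- length(signature_genes(bl, paste0("BL_", u)))
    nexc <- sum(bl$exclusions$signature == paste0("BL_", u))
    expect_equal(length(cand), nsig + nexc)
  }
})

test_that("OL-BL keeps only direction-consistent multi-line kinases", {
  genes <- c("ok_up", "flip", "solo")
  member_fs <- rbind(ok_up = c(TRUE, TRUE, FALSE),
                     flip = c(TRUE, TRUE, FALSE),
                     solo = c(TRUE, FALSE, FALSE))
  colnames(member_fs) <- paste0("L", 1:3)
  dir_fs <- ifelse(member_fs, "up", "none")
  member_ss <- member_fs
  dir_ss <- dir_fs
  dir_ss["flip", c(1, 2)] <- "down"  # up in FS, down in SS
  ol <- overlapping_bl(list(member = member_fs, direction = dir_fs),
                       list(member = member_ss, direction = dir_ss))
  expect_setequal(signature_genes(ol, "OL_BL"), "ok_up")
  expect_equal(ol$signatures$OL_BL$direction, "up")
  expect_equal(ol$exclusions$gene, "flip")
  expect_equal(ol$exclusions$reason, "direction-ambiguous")

  # random directional membership against hand enumeration on 12 genes
  set.seed(13)
  g12 <- sprintf("r%02d", 1:12)
  mfs <- matrix(runif(36) < 0.5, 12, 3, dimnames = list(g12, paste0("L", 1:3)))
  mss <- matrix(runif(36) < 0.5, 12, 3, dimnames = list(g12, paste0("L", 1:3)))
  dfs <- ifelse(mfs, sample(c("up", "down"), 36, replace = TRUE), "none")
  dss <- ifelse(mss, sample(c("up", "down"), 36, replace = TRUE), "none")
  ol2 <- overlapping_bl(list(member = mfs, direction = dfs),
                        list(member = mss, direction = dss))
  expected <- Filter(function(g) {
    if (sum(mfs[g, ]) < 2 || sum(mss[g, ]) < 2) return(FALSE)
    dd <- c(dfs[g, mfs[g, ]], dss[g, mss[g, ]])
    length(unique(dd)) == 1
  }, g12)
  expect_setequal(signature_genes(ol2, "OL_BL"), expected)
})

test_that("EGFRi signature applies ambiguity then uniqueness", {
  par <- toy_zprofiles(c("a_up", "b_shared", "c_conflict", "d_down"),
                       c("up", "up", "up", "down"),
                       c(TRUE, TRUE, TRUE, TRUE))
  res1 <- toy_zprofiles(c("b_shared", "c_conflict", "e_resist"),
                        c("up", "down", "up"), c(TRUE, TRUE, TRUE))
  sig <- egfri_signature(par, list(R1 = res1))
  # parental-only kinases split by direction
  expect_setequal(signature_genes(sig, "EGFRi_up"), "a_up")
  expect_setequal(signature_genes(sig, "EGFRi_down"), "d_down")
  # shared kinase excluded as not unique
  expect_equal(sig$exclusions$reason[sig$exclusions$gene == "b_shared"],
               "shared")
  # direction conflict removed before the uniqueness test
  expect_equal(sig$exclusions$reason[sig$exclusions$gene == "c_conflict"],
               "direction-ambiguous")
  # resistant-only kinases never enter
  expect_false("e_resist" %in% c(signature_genes(sig, "EGFRi_up"),
                                 signature_genes(sig, "EGFRi_down")))
  # up and down are disjoint
  expect_length(intersect(signature_genes(sig, "EGFRi_up"),
                          signature_genes(sig, "EGFRi_down")), 0)
})

test_that("signature comparison counts all pairwise intersections", {
  a <- signature_set(list(S1 = data.frame(gene = c("g1", "g2"),
                                          direction = NA_character_),
                          S2 = data.frame(gene = "g3",
                                          direction = NA_character_)),
                     c(S1 = "unique-BL", S2 = "unique-BL"))
  cmp <- compare_signatures(a)
  expect_equal(cmp$overlap[cmp$signature_a == "S1" & cmp$signature_b == "S2"],
               0)
  expect_equal(cmp$overlap[cmp$signature_a == "S1" & cmp$signature_b == "S1"],
               2)
  # random pairs against brute force
  set.seed(17)
  for (rep in 1:5) {
    g <- paste0("x", 1:30)
    s1 <- sample(g, 10); s2 <- sample(g, 12)
    ss <- signature_set(list(A = data.frame(gene = s1,
                                            direction = NA_character_),
                             B = data.frame(gene = s2,
                                            direction = NA_character_)),
                        c(A = "unique-BL", B = "unique-BL"))
    cmp2 <- compare_signatures(ss)
    expect_equal(cmp2$overlap[cmp2$signature_a == "A" &
                                cmp2$signature_b == "B"],
                 length(intersect(s1, s2)))
  }
})
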