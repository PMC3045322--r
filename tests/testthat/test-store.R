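test_that("the permission matrix reproduces the user-class table", {
  ## Independent hand-coded transcription of the four user classes:
  ## row-by-row over browse / edit / export / import / approve.
  oracle <- function(role, action, assigned, public, acceptedOnly) {
    browse <- switch(role,
      unregistered = public && acceptedOnly,
      registered = (public || assigned) && acceptedOnly,
      editor = assigned || (public && acceptedOnly),
      administrator = TRUE)
    switch(action,
      browse = browse,
      export = browse,
      edit = switch(role, administrator = TRUE, editor = assigned, FALSE),
      import = switch(role, administrator = TRUE, editor = assigned, FALSE),
      approve = role == "administrator")
  }
  roles <- c("unregistered", "registered", "editor", "administrator")
  actions <- c("browse", "edit", "export", "import", "approve")
  n <- 0
  for (role in roles) {
    for (action in actions) {
      for (assigned in c(TRUE, FALSE)) {
        if (assigned && role == "unregistered") next
        for (public in c(TRUE, FALSE)) {
          for (acceptedOnly in c(TRUE, FALSE)) {
            u <- user("u", role, if (assigned) "m1" else character(0))
            got <- checkPermission(u, action, "m1", public = public,
                                   acceptedOnly = acceptedOnly)
            expect_identical(got$allow,
                             oracle(role, action, assigned, public, acceptedOnly),
                             info = paste(role, action, assigned, public, acceptedOnly))
            expect_true(nzchar(got$reason))
            n <- n + 1
          }
        }
      }
    }
  }
  expect_gte(n, 4 * 5 * 2 * 2)  # exhaustive over the state space
})

test_that("pending changes stay invisible until an administrator approves", {
  st <- seededStore()
  ed <- getUser(st, "ed"); admin <- getUser(st, "admin"); reg <- getUser(st, "reg")

  ch <- proposeChange(st, ed, "tiny", "reaction", "update", entityId = "rh2o",
                      fields = list(name = "water synthase"), comment = "rename")
  expect_equal(ch$state, "pending")
  expect_equal(reactions(modelAtRevision(st, "tiny"))$rh2o$name, "water formation")

  ## registered users cannot edit; editors cannot touch unassigned models
  expect_error(proposeChange(st, reg, "tiny", "reaction", "update",
                             entityId = "rh2o", fields = list(name = "x")),
               class = "gsmv_permission_error")
  other <- user("ed2", "editor", assignedModels = "different_model")
  addUser(st, other)
  expect_error(proposeChange(st, other, "tiny", "reaction", "update",
                             entityId = "rh2o", fields = list(name = "x")),
               class = "gsmv_permission_error")

  ## editors cannot approve; empty approval set is an argument error
  expect_error(approveChanges(st, ch$changeId, ed), class = "gsmv_permission_error")
  expect_error(approveChanges(st, character(0), admin), class = "gsmv_argument_error")

  before <- currentRevision(st)
  rev <- approveChanges(st, ch$changeId, admin)
  expect_equal(rev$number, before + 1)
  expect_equal(reactions(modelAtRevision(st, "tiny"))$rh2o$name, "water synthase")
  expect_equal(reactions(modelAtRevision(st, "tiny", before))$rh2o$name,
               "water formation")
  expect_error(approveChanges(st, ch$changeId, admin), class = "gsmv_state_error")

  ## malformed delta
  expect_error(proposeChange(st, ed, "tiny", "reaction", "update",
                             entityId = "rh2o", fields = list(nonexistent = 1)),
               class = "gsmv_argument_error")
})

test_that("two approved edits land in one revision and labels auto-increment", {
  st <- seededStore()
  ed <- getUser(st, "ed"); admin <- getUser(st, "admin")
  c1 <- proposeChange(st, ed, "tiny", "metabolite", "update", entityId = "h2",
                      fields = list(name = "dihydrogen"))
  c2 <- proposeChange(st, ed, "tiny", "gene", "update", entityId = "g1",
                      fields = list(name = "hydrogenase subunit"))
  rev <- approveChanges(st, c(c1$changeId, c2$changeId), admin)
  m <- modelAtRevision(st, "tiny")
  expect_equal(metabolites(m)$h2$name, "dihydrogen")
  expect_equal(genes(m)$g1$name, "hydrogenase subunit")
  expect_equal(versionLabel(m), "2")  # publish was "1"
  ## explicit label
  c3 <- proposeChange(st, ed, "tiny", "gene", "update", entityId = "g1",
                      fields = list(name = "HydA"))
  approveChanges(st, c3$changeId, admin, versionLabel = "v2.0-draft")
  expect_equal(versionLabel(modelAtRevision(st, "tiny")), "v2.0-draft")
})

test_that("snapshots equal a deep-copy-per-revision oracle over random histories", {
  set.seed(99)
  st <- modelStore(clock = fixedClock())
  admin <- user("boss", "administrator"); addUser(st, admin)
  mid <- "hist"
  subsPool <- c("s1", "s2")

  ## oracle state: plain records the harness edits directly
  oracle <- list(
    info = list(name = "history model", organism = "Synthetica historica",
                notes = "", subsystems = subsPool, annotations = character(0)),
    compartments = list(c0 = compartment("c0", "cytoplasm")),
    metabolites = list(), genes = list(), reactions = list())
  snapshots <- list()

  proposeChange(st, admin, mid, "model", "create", value = oracle$info)
  proposeChange(st, admin, mid, "compartment", "create",
                value = oracle$compartments$c0)
  pendingIds <- NULL  # approve everything pending at approval steps

  nMet <- 0; nGene <- 0; nRxn <- 0
  for (step in 1:120) {
    op <- sample(c("createMet", "createGene", "createRxn", "update", "delete",
                   "approve"), 1,
                 prob = c(0.2, 0.15, 0.1, 0.25, 0.1, 0.2))
    if (op == "createMet") {
      nMet <- nMet + 1
      rec <- metabolite(sprintf("m%03d", nMet), name = sprintf("met %d", nMet),
                        formula = "C2H4")
      oracle$metabolites[[rec$abbreviation]] <- rec
      proposeChange(st, admin, mid, "metabolite", "create", value = rec)
    } else if (op == "createGene") {
      nGene <- nGene + 1
      rec <- gene(sprintf("g%03d", nGene))
      oracle$genes[[rec$abbreviation]] <- rec
      proposeChange(st, admin, mid, "gene", "create", value = rec)
    } else if (op == "createRxn" && length(oracle$metabolites) >= 2) {
      nRxn <- nRxn + 1
      mets <- sample(names(oracle$metabolites), 2)
      rec <- reaction(sprintf("r%03d", nRxn), reactants = rbind(
        reactants(mets[1], 1, "c0", "substrate"),
        reactants(mets[2], 1, "c0", "product")),
        subsystem = sample(subsPool, 1))
      oracle$reactions[[rec$abbreviation]] <- rec
      proposeChange(st, admin, mid, "reaction", "create", value = rec)
    } else if (op == "update") {
      kind <- sample(c("metabolite", "gene"), 1)
      slot <- paste0(kind, "s")
      ## only edit entities already visible (accepted or pending-created)
      pool <- names(oracle[[slot]])
      if (length(pool)) {
        id <- sample(pool, 1)
        newName <- sprintf("renamed %s %d", id, step)
        oracle[[slot]][[id]]["name"] <- list(newName)
        proposeChange(st, admin, mid, kind, "update", entityId = id,
                      fields = list(name = newName), comment = sprintf("step %d", step))
      }
    } else if (op == "delete") {
      ## delete a gene that is not referenced anywhere
      pool <- names(oracle$genes)
      if (length(pool)) {
        id <- sample(pool, 1)
        oracle$genes[[id]] <- NULL
        proposeChange(st, admin, mid, "gene", "delete", entityId = id)
      }
    } else if (op == "approve") {
      pend <- pendingChanges(st, admin, mid)
      if (length(pend)) {
        approveChanges(st, vapply(pend, function(ch) ch$changeId, character(1)),
                       admin)
        snapshots[[length(snapshots) + 1L]] <- oracle  # deep copy by value
      }
    }
  }
  pend <- pendingChanges(st, admin, mid)
  if (length(pend)) {
    approveChanges(st, vapply(pend, function(ch) ch$changeId, character(1)), admin)
    snapshots[[length(snapshots) + 1L]] <- oracle
  }

  expect_equal(currentRevision(st), length(snapshots))
  for (r in seq_along(snapshots)) {
    snap <- snapshots[[r]]
    expected <- metabolicModel(mid, name = snap$info$name,
      organism = snap$info$organism,
      compartments = unname(snap$compartments),
      metabolites = unname(snap$metabolites[sort(names(snap$metabolites))]),
      reactions = unname(snap$reactions[sort(names(snap$reactions))]),
      genes = unname(snap$genes[sort(names(snap$genes))]),
      subsystems = snap$info$subsystems, versionLabel = as.character(r))
    expect_equal(modelAtRevision(st, mid, r), expected, info = sprintf("revision %d", r))
  }
  ## head equals the last snapshot; revisions are gapless 1..N
  expect_equal(modelAtRevision(st, mid), modelAtRevision(st, mid, length(snapshots)))
})

test_that("entity history lists diffs and replays to the head state", {
  st <- seededStore()
  ed <- getUser(st, "ed"); admin <- getUser(st, "admin")
  h0 <- entityHistory(st, "tiny", "metabolite", "h2o")
  expect_length(h0$entries, 1)
  expect_equal(h0$entries[[1]]$action, "create")

  ch <- proposeChange(st, ed, "tiny", "metabolite", "update", entityId = "h2o",
                      fields = list(name = "H2O", charge = 0L), comment = "tidy")
  approveChanges(st, ch$changeId, admin)
  h1 <- entityHistory(st, "tiny", "metabolite", "h2o")
  expect_length(h1$entries, 2)
  expect_setequal(names(h1$entries[[2]]$diffs), c("name", "charge"))
  expect_equal(h1$entries[[2]]$comment, "tidy")
  expect_equal(replayHistory(h1), metabolites(modelAtRevision(st, "tiny"))$h2o)

  expect_error(entityHistory(st, "tiny", "metabolite", "ghost"),
               class = "gsmv_notfound_error")

  ## rejected changes never enter history
  ch2 <- proposeChange(st, ed, "tiny", "metabolite", "update", entityId = "h2o",
                       fields = list(name = "scrapped"))
  rejectChanges(st, ch2$changeId, admin)
  expect_length(entityHistory(st, "tiny", "metabolite", "h2o")$entries, 2)
  expect_equal(metabolites(modelAtRevision(st, "tiny"))$h2o$name, "H2O")
})

test_that("browse views respect roles and pending material stays hidden", {
  st <- seededStore()
  admin <- getUser(st, "admin")
  ## model starts private: guests are denied, registered assigned users pass
  expect_error(browseModel(st, getUser(st, "guest"), "tiny"),
               class = "gsmv_permission_error")
  expect_s4_class(browseModel(st, getUser(st, "reg"), "tiny"), "MetabolicModel")
  setModelPublic(st, "tiny", TRUE, admin)
  expect_s4_class(browseModel(st, getUser(st, "guest"), "tiny"), "MetabolicModel")
  ## non-admins cannot flip visibility
  expect_error(setModelPublic(st, "tiny", FALSE, getUser(st, "ed")),
               class = "gsmv_permission_error")
  ## pending change listing requires access to unaccepted material
  proposeChange(st, getUser(st, "ed"), "tiny", "gene", "update", entityId = "g1",
                fields = list(name = "draft name"))
  expect_error(pendingChanges(st, getUser(st, "reg"), "tiny"),
               class = "gsmv_permission_error")
  expect_length(pendingChanges(st, getUser(st, "ed"), "tiny"), 1)
  ## and the guest's accepted view never contains it
  expect_equal(genes(browseModel(st, getUser(st, "guest"), "tiny"))$g1$name,
               "gene one")
})

test_that("a store survives the write/read round trip", {
  st <- seededStore()
  ed <- getUser(st, "ed"); admin <- getUser(st, "admin")
  ch <- proposeChange(st, ed, "tiny", "reaction", "update", entityId = "rtrans",
                      fields = list(reversible = FALSE), comment = "direction fixed")
  approveChanges(st, ch$changeId, admin, versionLabel = "curated")
  addComment(st, ed, "tiny", "should we keep this transporter?",
             kind = "reaction", entityId = "rtrans")
  path <- withr::local_tempfile(fileext = ".json")
  writeStore(st, path)
  st2 <- readStore(path, clock = fixedClock())
  expect_equal(currentRevision(st2), currentRevision(st))
  for (r in seq_len(currentRevision(st)))
    expect_equal(modelAtRevision(st2, "tiny", r), modelAtRevision(st, "tiny", r))
  expect_equal(storeUsers(st2), storeUsers(st))
  expect_length(listComments(st2, "tiny", "reaction", "rtrans"), 1)
  expect_equal(entityHistory(st2, "tiny", "reaction", "rtrans"),
               entityHistory(st, "tiny", "reaction", "rtrans"))
  expect_error(readStore(withr::local_tempfile()), class = "gsmv_notfound_error")
})
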