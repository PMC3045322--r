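## Role-based access control.
##
## Four user classes govern what may be browsed, edited, exported, imported
## and approved:
##   unregistered  - accepted versions of publicly available models only
##   registered    - additionally accepted versions of assigned models
##   editor        - all versions of assigned models; edit/import on assigned
##   administrator - everything, including modification approval
## Export is allowed to every class on any model view the class may browse.

userRoles <- c("unregistered", "registered", "editor", "administrator")
userActions <- c("browse", "edit", "export", "import", "approve")

#' Create a user record
#'
#' Users are declarative records (no authentication): a username, one of the
#' four roles, and the set of models the user is assigned to. Unregistered
#' users cannot hold assignments.
#'
#' @param username Unique name within a store.
#' @param role One of `"unregistered"`, `"registered"`, `"editor"`,
#'   `"administrator"`.
#' @param assignedModels Character vector of model ids.
#' @return A user record (named list).
#' @export
user <- function(username, role = "registered", assignedModels = character(0)) {
  role <- match.arg(role, userRoles)
  if (!is.character(username) || length(username) != 1L || !nzchar(username))
    gsmvArgError("username must be a non-empty string")
  if (role == "unregistered" && length(assignedModels))
    gsmvArgError("unregistered users cannot have assigned models")
  structure(list(username = username, role = role,
                 assignedModels = as.character(assignedModels)),
            class = "gsmUser")
}

#' Permission decision for a user, action and model view
#'
#' Pure decision function over the user-class table. The target model view is
#' described by its public availability and whether the requested view is the
#' accepted state only (`acceptedOnly = FALSE` means access to unapproved /
#' pending material, which only editors of the model and administrators get).
#'
#' @param usr A record from [user()].
#' @param action One of `"browse"`, `"edit"`, `"export"`, `"import"`,
#'   `"approve"`.
#' @param targetModel Model id (may be `NA` for approve).
#' @param public Is the model publicly available?
#' @param acceptedOnly Does the request touch only the accepted state?
#' @return List with `allow` (logical) and `reason` (string).
#' @export
#' @examples
#' checkPermission(user("guest", "unregistered"), "browse", "m1", public = TRUE)
checkPermission <- function(usr, action, targetModel = NA_character_,
                            public = TRUE, acceptedOnly = TRUE) {
  action <- match.arg(action, userActions)
  if (!inherits(usr, "gsmUser")) gsmvArgError("usr must come from user()")
  assigned <- !is.na(targetModel) && targetModel %in% usr$assignedModels
  decision <- function(allow, reason) list(allow = allow, reason = reason)

  browseDecision <- function() {
    switch(usr$role,
      administrator = decision(TRUE, "administrators access all models"),
      editor = if (assigned)
        decision(TRUE, "editors browse all versions of assigned models")
      else if (public && acceptedOnly)
        decision(TRUE, "accepted versions of public models are browsable")
      else decision(FALSE, "editors only reach unaccepted material of assigned models"),
      registered = if (acceptedOnly && (public || assigned))
        decision(TRUE, "registered users browse accepted versions of public and assigned models")
      else decision(FALSE, "registered users see accepted versions of public/assigned models only"),
      unregistered = if (acceptedOnly && public)
        decision(TRUE, "accepted versions of public models are browsable")
      else decision(FALSE, "unregistered visitors see accepted versions of public models only")
    )
  }

  switch(action,
    browse = browseDecision(),
    export = {
      d <- browseDecision()
      if (d$allow) decision(TRUE, paste("export follows browse:", d$reason))
      else decision(FALSE, paste("export follows browse:", d$reason))
    },
    edit = switch(usr$role,
      administrator = decision(TRUE, "administrators edit all models"),
      editor = if (assigned) decision(TRUE, "editors edit assigned models")
               else decision(FALSE, "model is not assigned to this editor"),
      decision(FALSE, sprintf("%s users cannot edit models", usr$role))),
    import = switch(usr$role,
      administrator = decision(TRUE, "administrators import into all models"),
      editor = if (assigned) decision(TRUE, "editors import into assigned models")
               else decision(FALSE, "model is not assigned to this editor"),
      decision(FALSE, sprintf("%s users cannot import models", usr$role))),
    approve = if (usr$role == "administrator")
      decision(TRUE, "administrators approve modifications")
    else decision(FALSE, "only administrators approve modifications")
  )
}
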