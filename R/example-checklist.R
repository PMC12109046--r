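#' Example waterbird checklist (synthetic reference assemblage)
#'
#' A 45-species checklist assembled in code, representative of a restored
#' South-East Asian wetland on the East Asian-Australasian Flyway. Its
#' taxonomic composition carries the canonical worked-example shares used
#' throughout the documentation and tests: 13 Charadriiformes (28.89%),
#' 12 Pelecaniformes (26.67%, of which 9 Ardeidae = 20%), 7 Anseriformes
#' (15.56%), 4 Gruiformes (8.89%), and 7 threat-listed species (15.6%: two
#' EN, three VU, two NT), across 11 orders. Guilds follow
#' [guildReference()] with wetland-typical assignments for species outside
#' the bundled table. This is a synthetic reference object, not field data.
#'
#' @return a [Checklist-class] of 45 species.
#' @examples
#' cl <- exampleChecklist()
#' taxonShares(cl, rank = "order")
#' @export
exampleChecklist <- function() {
  row <- function(species, genus, family, order, guild, iucn, prot = FALSE)
    data.frame(species = species, genus = genus, family = family,
               order = order, guild = guild, iucn_status = iucn,
               protected = prot, stringsAsFactors = FALSE)
  sco <- function(sp, g, guild = "small_wader", iucn = "LC")
    row(sp, g, "Scolopacidae", "Charadriiformes", guild, iucn)
  ard <- function(sp, g, prot = FALSE)
    row(sp, g, "Ardeidae", "Pelecaniformes", "large_wader", "LC", prot)
  ana <- function(sp, g, guild = "dabbling", iucn = "LC", prot = FALSE)
    row(sp, g, "Anatidae", "Anseriformes", guild, iucn, prot)

  taxa <- rbind(
    # Charadriiformes (13)
    sco("Calidris tenuirostris", "Calidris", iucn = "EN"),
    sco("Calidris temminckii", "Calidris"),
    sco("Gallinago gallinago", "Gallinago"),
    sco("Limosa limosa", "Limosa", iucn = "NT"),
    sco("Tringa ochropus", "Tringa"),
    sco("Tringa glareola", "Tringa"),
    sco("Tringa totanus", "Tringa"),
    sco("Actitis hypoleucos", "Actitis"),
    row("Charadrius dubius", "Charadrius", "Charadriidae",
        "Charadriiformes", "small_wader", "LC"),
    row("Charadrius veredus", "Charadrius", "Charadriidae",
        "Charadriiformes", "small_wader", "LC"),
    row("Pluvialis fulva", "Pluvialis", "Charadriidae", "Charadriiformes",
        "small_wader", "LC"),
    row("Vanellus cinereus", "Vanellus", "Charadriidae", "Charadriiformes",
        "small_wader", "LC"),
    row("Himantopus himantopus", "Himantopus", "Recurvirostridae",
        "Charadriiformes", "small_wader", "LC"),
    # Pelecaniformes (12): 9 Ardeidae + Threskiornithidae + Pelecanidae
    ard("Ardea cinerea", "Ardea"),
    ard("Ardea purpurea", "Ardea"),
    ard("Egretta garzetta", "Egretta"),
    ard("Mesophoyx intermedia", "Mesophoyx"),
    ard("Bubulcus ibis", "Bubulcus"),
    ard("Ixobrychus cinnamomeus", "Ixobrychus", prot = TRUE),
    ard("Casmerodius albus", "Casmerodius"),
    ard("Nycticorax nycticorax", "Nycticorax"),
    ard("Ardeola grayii", "Ardeola"),
    row("Platalea minor", "Platalea", "Threskiornithidae", "Pelecaniformes",
        "large_wader", "EN"),
    row("Threskiornis melanocephalus", "Threskiornis", "Threskiornithidae",
        "Pelecaniformes", "large_wader", "LC"),
    row("Pelecanus philippensis", "Pelecanus", "Pelecanidae",
        "Pelecaniformes", "large_wader", "NT", TRUE),
    # Anseriformes (7, all Anatidae)
    ana("Anas acuta", "Anas", prot = TRUE),
    ana("Anas crecca", "Anas", prot = TRUE),
    ana("Anas querquedula", "Anas", prot = TRUE),
    ana("Anas luzonica", "Anas", iucn = "VU"),
    ana("Dendrocygna javanica", "Dendrocygna", prot = TRUE),
    ana("Nettapus coromandelianus", "Nettapus", prot = TRUE),
    ana("Tadorna ferruginea", "Tadorna", prot = TRUE),
    # Gruiformes (4)
    row("Grus vipio", "Grus", "Gruidae", "Gruiformes", "large_wader", "VU"),
    row("Porphyrio porphyrio", "Porphyrio", "Rallidae", "Gruiformes",
        "none", "LC"),
    row("Amaurornis phoenicurus", "Amaurornis", "Rallidae", "Gruiformes",
        "none", "LC"),
    row("Gallinula chloropus", "Gallinula", "Rallidae", "Gruiformes",
        "none", "LC"),
    # seven further orders (9 species)
    row("Podiceps cristatus", "Podiceps", "Podicipedidae",
        "Podicipediformes", "diving", "VU"),
    row("Tachybaptus ruficollis", "Tachybaptus", "Podicipedidae",
        "Podicipediformes", "diving", "LC", TRUE),
    row("Phalacrocorax carbo", "Phalacrocorax", "Phalacrocoracidae",
        "Suliformes", "diving", "LC"),
    row("Phalacrocorax niger", "Phalacrocorax", "Phalacrocoracidae",
        "Suliformes", "large_wader", "LC"),
    row("Anhinga melanogaster", "Anhinga", "Anhingidae", "Anhingiformes",
        "diving", "LC", TRUE),
    row("Anastomus oscitans", "Anastomus", "Ciconiidae", "Ciconiiformes",
        "large_wader", "LC"),
    row("Alcedo atthis", "Alcedo", "Alcedinidae", "Coraciiformes",
        "none", "LC"),
    row("Motacilla alba", "Motacilla", "Motacillidae", "Passeriformes",
        "none", "LC"),
    row("Haliastur indus", "Haliastur", "Accipitridae", "Accipitriformes",
        "none", "LC"))
  Checklist(taxa)
}
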