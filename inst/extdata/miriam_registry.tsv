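# MIRIAM datatype registry: maps datatype keys to URL templates.
# Add rows (or c() entries onto the loaded vector) to register further
# external databases. {id} is replaced by the percent-encoded identifier.
datatype	url_template
chebi	https://identifiers.org/chebi/{id}
kegg.compound	https://identifiers.org/kegg.compound/{id}
kegg.reaction	https://identifiers.org/kegg.reaction/{id}
kegg.genes	https://identifiers.org/kegg.genes/{id}
kegg.pathway	https://identifiers.org/kegg.pathway/{id}
ec-code	https://identifiers.org/ec-code/{id}
uniprot	https://identifiers.org/uniprot/{id}
pubmed	https://identifiers.org/pubmed/{id}
doi	https://identifiers.org/doi/{id}
go	https://identifiers.org/go/{id}
taxonomy	https://identifiers.org/taxonomy/{id}
pubchem.compound	https://identifiers.org/pubchem.compound/{id}
rhea	https://identifiers.org/rhea/{id}
pdb	https://identifiers.org/pdb/{id}
interpro	https://identifiers.org/interpro/{id}
sbo	https://identifiers.org/sbo/{id}
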