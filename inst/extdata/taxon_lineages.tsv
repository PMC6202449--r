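label	lineage
Bacteria	Bacteria
Cyanobacteria	Bacteria;Cyanobacteria
Snowella	Bacteria;Cyanobacteria;Snowella
Synechococcus	Bacteria;Cyanobacteria;Synechococcus
Leptolyngbya	Bacteria;Cyanobacteria;Leptolyngbya
Phormidium	Bacteria;Cyanobacteria;Phormidium
FamilyI	Bacteria;Cyanobacteria;FamilyI
Proteobacteria	Bacteria;Proteobacteria
Alphaproteobacteria	Bacteria;Proteobacteria;Alphaproteobacteria
Betaproteobacteria	Bacteria;Proteobacteria;Betaproteobacteria
Gammaproteobacteria	Bacteria;Proteobacteria;Gammaproteobacteria
Sphingomonadales	Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales
Sphingomonadaceae	Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae
Polymorphobacter	Bacteria;Proteobacteria;Alphaproteobacteria;Sphingomonadales;Sphingomonadaceae;Polymorphobacter
Rhizobiales	Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales
Devosia	Bacteria;Proteobacteria;Alphaproteobacteria;Rhizobiales;Devosia
Brevundimonas	Bacteria;Proteobacteria;Alphaproteobacteria;Caulobacterales;Caulobacteraceae;Brevundimonas
Rhodobacteraceae	Bacteria;Proteobacteria;Alphaproteobacteria;Rhodobacterales;Rhodobacteraceae
Burkholderiales	Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales
Hydrogenophaga	Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Comamonadaceae;Hydrogenophaga
Limnobacter	Bacteria;Proteobacteria;Betaproteobacteria;Burkholderiales;Burkholderiaceae;Limnobacter
Xanthomonadaceae	Bacteria;Proteobacteria;Gammaproteobacteria;Xanthomonadales;Xanthomonadaceae
Arenimonas	Bacteria;Proteobacteria;Gammaproteobacteria;Xanthomonadales;Xanthomonadaceae;Arenimonas
Pseudomonas	Bacteria;Proteobacteria;Gammaproteobacteria;Pseudomonadales;Pseudomonadaceae;Pseudomonas
Bacteroidetes	Bacteria;Bacteroidetes
Flavobacteriaceae	Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae
Flavobacterium	Bacteria;Bacteroidetes;Flavobacteriia;Flavobacteriales;Flavobacteriaceae;Flavobacterium
Cytophagales	Bacteria;Bacteroidetes;Cytophagia;Cytophagales
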