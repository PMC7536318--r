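ref_id	domain	phylum	class	order	family	genus
SYNREF01	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfobacterales	Desulfobacteraceae	Desulfobacula
SYNREF02	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfobacterales	Desulfobacteraceae	Desulfobacula
SYNREF03	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfobacterales	Desulfobacteraceae	Desulfobacterium
SYNREF04	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfobacterales	Desulfobacteraceae	Desulfatibacillum
SYNREF05	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfobacterales	Desulfobulbaceae	Desulfobulbus
SYNREF06	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfobacterales	Desulfobulbaceae	Desulfobulbus
SYNREF07	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfobacterales	Desulfobulbaceae	Desulfotalea
SYNREF08	Bacteria	Proteobacteria	Deltaproteobacteria	Desulfobacterales	Desulfobulbaceae	Desulforhopalus
SYNREF09	Bacteria	Spirochaetes	Spirochaetia	Spirochaetales	Treponemataceae	Treponema
SYNREF10	Bacteria	Spirochaetes	Spirochaetia	Spirochaetales	Treponemataceae	Treponema
SYNREF11	Bacteria	Spirochaetes	Spirochaetia	Spirochaetales	Treponemataceae	Spirochaeta
SYNREF12	Bacteria	Spirochaetes	Spirochaetia	Spirochaetales	Treponemataceae	Sediminispirochaeta
SYNREF13	Bacteria	Firmicutes	Clostridia	Eubacteriales	Peptococcaceae	Desulfosporosinus
SYNREF14	Bacteria	Firmicutes	Clostridia	Eubacteriales	Peptococcaceae	Desulfosporosinus
SYNREF15	Bacteria	Firmicutes	Clostridia	Eubacteriales	Peptococcaceae	Desulfitobacterium
SYNREF16	Bacteria	Firmicutes	Clostridia	Eubacteriales	Peptococcaceae	Dehalobacter
SYNREF17	Archaea	Euryarchaeota	Methanomicrobia	Methanomicrobiales	Methanoregulaceae	Methanoregula
SYNREF18	Archaea	Euryarchaeota	Methanomicrobia	Methanomicrobiales	Methanoregulaceae	Methanoregula
SYNREF19	Archaea	Euryarchaeota	Methanomicrobia	Methanomicrobiales	Methanoregulaceae	Methanosphaerula
SYNREF20	Archaea	Euryarchaeota	Methanomicrobia	Methanomicrobiales	Methanoregulaceae	Methanolinea
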