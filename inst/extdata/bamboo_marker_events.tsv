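event	kind	locus	region	length_bp	shared_insert_bp	extension_3p_bp	extension_3p_results_bp	clade	taxa	flank_repeat
parianinae_mito_insertion	insertion	rpl23-ndhB	IR	4938	2706	2232	1242	Parianinae	Eremitis sp.,Pariana radiciflora	NA
guaduinae_deletion	deletion	rpl23-ndhB region	IR	1500	NA	NA	NA	Guaduinae	Guadua weberbaueri,Olmeca reflexa,Otatea acuminata	NA
olyrinae_inversion	inversion	trnD-psbM	LSC	150	NA	NA	NA	Olyrinae	Cryptochloa strictiflora,Diandrolyra sp.,Lithachne pauciflora,Olyra latifolia,Raddia brasiliensis	CCYTTTTY
arundinarieae_insertion	insertion	rps16-trnQ	LSC	500	NA	NA	NA	Arundinarieae	Acidosasa purpurea,Arundinaria appalachiana,Arundinaria gigantea,Arundinaria tecta,Ferrocalamus rimosivaginus,Indocalamus longiauritus,Phyllostachys edulis,Phyllostachys nigra,Phyllostachys propinqua,Thamnocalamus spathiflorus	NA
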