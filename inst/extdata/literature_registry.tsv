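species	hosts	host_group	is_parasite	citation
Rhizophydium littoreum	Cancer anthonyi	zooplankton	TRUE	published host record
Zygophlyctis planktonica	Synedra sp.	phytoplankton	TRUE	published host record
Zygophlyctis melosirae	Aulacoseira sp.	phytoplankton	TRUE	published host record
Gaertneriomyces semiglobifer	Entomophaga maimaiga	fungi	TRUE	published host record
Dangeardia mamillata	Yamagishiella unicocca	phytoplankton	TRUE	published host record
Chlamydomyzium dictyuchoides	nematodes	nematodes	TRUE	published host record
Chytriodinium roseum	Meganyctiphanes norvegica	zooplankton	TRUE	published host record
Rhizophydium planktonicum	Asterionella formosa	phytoplankton	TRUE	published host record
Parvilucifera infectans		Various	TRUE	published host record
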