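# Synthetic Spanish-surname fixture for tests and examples.
# Two columns: SURNAME<TAB>CATEGORY. Categories follow the five-tier
# scheme (HEAVILY, GENERALLY, MODERATELY, OCCASIONALLY, RARELY).
# This toy list is NOT the 1990 U.S. Census Spanish Surname List; supply
# the full list via load_surname_table(path) for production use.
GARCIA	HEAVILY
RODRIGUEZ	HEAVILY
MARTINEZ	HEAVILY
HERNANDEZ	HEAVILY
LOPEZ	HEAVILY
GONZALEZ	HEAVILY
PEREZ	HEAVILY
SANCHEZ	HEAVILY
RAMIREZ	HEAVILY
TORRES	HEAVILY
FLORES	HEAVILY
RIVERA	HEAVILY
GOMEZ	HEAVILY
DIAZ	HEAVILY
CRUZ	HEAVILY
DE LA CRUZ	HEAVILY
VASQUEZ	HEAVILY
GUTIERREZ	HEAVILY
ORTIZ	GENERALLY
MORALES	GENERALLY
REYES	GENERALLY
JIMENEZ	GENERALLY
RUIZ	GENERALLY
ALVAREZ	GENERALLY
CASTILLO	GENERALLY
ROMERO	GENERALLY
MENDOZA	GENERALLY
MEDINA	MODERATELY
AGUILAR	MODERATELY
SILVA	MODERATELY
CASTRO	MODERATELY
VARGAS	MODERATELY
SOTO	MODERATELY
MOLINA	MODERATELY
LEON	OCCASIONALLY
DURAN	OCCASIONALLY
MARIN	OCCASIONALLY
ROCHA	OCCASIONALLY
MACIAS	OCCASIONALLY
SALAS	OCCASIONALLY
MARQUES	OCCASIONALLY
COSTA	RARELY
MARTIN	RARELY
SIMON	RARELY
GIL	RARELY
VIDAL	RARELY
SERRA	RARELY
PINTO	RARELY
ROCA	RARELY
FERRER	RARELY
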