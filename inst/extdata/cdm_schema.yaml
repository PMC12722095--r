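# Reduced 8-table core of a PCORnet-style common data model.
# Field layouts and value sets follow publicly documented CDM conventions
# (e.g. ENC_TYPE AV/ED/EI/IP/IS/OA/OS; SEX F/M/OT/UN); the schema is
# config-driven so tables and fields can be added without code changes.
version: "core-8table-v1"
required_tables: [DEMOGRAPHIC, ENCOUNTER, DIAGNOSIS]
value_sets:
  SEX:
    description: Administrative sex
    codes: [F, M, OT, UN, NI]
  HISPANIC:
    description: Hispanic ethnicity flag
    codes: ["Y", "N", "R", "OT", "UN", "NI"]
  RACE:
    description: Race (CDM coded)
    codes: ["01", "02", "03", "04", "05", "06", "07", OT, UN, NI]
  ENC_TYPE:
    description: Encounter type
    codes: [AV, ED, EI, IP, IS, OA, OS, TH, OT, UN, NI]
  DISCHARGE_DISPOSITION:
    description: Vital status at discharge (A alive, E expired)
    codes: [A, E, OT, UN, NI]
  DX_TYPE:
    description: Diagnosis code type ("09" ICD-9-CM, "10" ICD-10-CM)
    codes: ["09", "10", SM, OT, UN, NI]
  PDX:
    description: Principal diagnosis flag (P principal, S secondary)
    codes: [P, S, X, OT, UN, NI]
  PX_TYPE:
    description: Procedure code type (CH = CPT/HCPCS)
    codes: ["09", "10", CH, LC, ND, OT, UN, NI]
  DEATH_SOURCE:
    description: Source of the death record
    codes: ["L", "N", "D", "S", "T", "OT", "UN", "NI"]
tables:
  DEMOGRAPHIC:
    primary_key: PATID
    date_field: null
    fields:
      - {name: PATID, kind: identifier, required: true, nullable: false}
      - {name: BIRTH_DATE, kind: date, required: true, nullable: true}
      - {name: SEX, kind: coded, value_set: SEX, required: true, nullable: true}
      - {name: HISPANIC, kind: coded, value_set: HISPANIC, required: false, nullable: true}
      - {name: RACE, kind: coded, value_set: RACE, required: false, nullable: true}
  ENCOUNTER:
    primary_key: ENCOUNTERID
    date_field: ADMIT_DATE
    fields:
      - {name: ENCOUNTERID, kind: identifier, required: true, nullable: false}
      - name: PATID
        kind: identifier
        required: true
        nullable: false
        references: {table: DEMOGRAPHIC, field: PATID}
      - {name: ADMIT_DATE, kind: date, required: true, nullable: true}
      - {name: DISCHARGE_DATE, kind: date, required: false, nullable: true}
      - {name: ENC_TYPE, kind: coded, value_set: ENC_TYPE, required: true, nullable: true}
      - {name: FACILITYID, kind: text, required: false, nullable: true}
      - name: DISCHARGE_DISPOSITION
        kind: coded
        value_set: DISCHARGE_DISPOSITION
        required: false
        nullable: true
  DIAGNOSIS:
    primary_key: DIAGNOSISID
    date_field: DX_DATE
    fields:
      - {name: DIAGNOSISID, kind: identifier, required: true, nullable: false}
      - name: PATID
        kind: identifier
        required: true
        nullable: false
        references: {table: DEMOGRAPHIC, field: PATID}
      - name: ENCOUNTERID
        kind: identifier
        required: true
        nullable: true
        references: {table: ENCOUNTER, field: ENCOUNTERID}
      - {name: DX, kind: text, required: true, nullable: true}
      - {name: DX_TYPE, kind: coded, value_set: DX_TYPE, required: true, nullable: true}
      - {name: DX_DATE, kind: date, required: true, nullable: true}
      - {name: PDX, kind: coded, value_set: PDX, required: false, nullable: true}
  PROCEDURES:
    primary_key: PROCEDURESID
    date_field: PX_DATE
    fields:
      - {name: PROCEDURESID, kind: identifier, required: true, nullable: false}
      - name: PATID
        kind: identifier
        required: true
        nullable: false
        references: {table: DEMOGRAPHIC, field: PATID}
      - name: ENCOUNTERID
        kind: identifier
        required: true
        nullable: true
        references: {table: ENCOUNTER, field: ENCOUNTERID}
      - {name: PX, kind: text, required: true, nullable: true}
      - {name: PX_TYPE, kind: coded, value_set: PX_TYPE, required: true, nullable: true}
      - {name: PX_DATE, kind: date, required: true, nullable: true}
  PRESCRIBING:
    primary_key: PRESCRIBINGID
    date_field: RX_ORDER_DATE
    fields:
      - {name: PRESCRIBINGID, kind: identifier, required: true, nullable: false}
      - name: PATID
        kind: identifier
        required: true
        nullable: false
        references: {table: DEMOGRAPHIC, field: PATID}
      - name: ENCOUNTERID
        kind: identifier
        required: false
        nullable: true
        references: {table: ENCOUNTER, field: ENCOUNTERID}
      - {name: RX_ORDER_DATE, kind: date, required: true, nullable: true}
      - {name: RXNORM_CUI, kind: text, required: true, nullable: true}
      - {name: RX_DAYS_SUPPLY, kind: numeric, required: false, nullable: true}
      - {name: RX_QUANTITY, kind: numeric, required: false, nullable: true}
  LAB_RESULT_CM:
    primary_key: LAB_RESULT_CM_ID
    date_field: RESULT_DATE
    fields:
      - {name: LAB_RESULT_CM_ID, kind: identifier, required: true, nullable: false}
      - name: PATID
        kind: identifier
        required: true
        nullable: false
        references: {table: DEMOGRAPHIC, field: PATID}
      - name: ENCOUNTERID
        kind: identifier
        required: false
        nullable: true
        references: {table: ENCOUNTER, field: ENCOUNTERID}
      - {name: LAB_LOINC, kind: text, required: true, nullable: true}
      - {name: RESULT_DATE, kind: date, required: true, nullable: true}
      - {name: RESULT_NUM, kind: numeric, required: false, nullable: true}
      - {name: RESULT_UNIT, kind: text, required: false, nullable: true}
  VITAL:
    primary_key: VITALID
    date_field: MEASURE_DATE
    fields:
      - {name: VITALID, kind: identifier, required: true, nullable: false}
      - name: PATID
        kind: identifier
        required: true
        nullable: false
        references: {table: DEMOGRAPHIC, field: PATID}
      - name: ENCOUNTERID
        kind: identifier
        required: false
        nullable: true
        references: {table: ENCOUNTER, field: ENCOUNTERID}
      - {name: MEASURE_DATE, kind: date, required: true, nullable: true}
      - {name: HT, kind: numeric, required: false, nullable: true}
      - {name: WT, kind: numeric, required: false, nullable: true}
      - {name: SYSTOLIC, kind: numeric, required: false, nullable: true}
      - {name: DIASTOLIC, kind: numeric, required: false, nullable: true}
  DEATH:
    primary_key: PATID
    date_field: null
    fields:
      - name: PATID
        kind: identifier
        required: true
        nullable: false
        references: {table: DEMOGRAPHIC, field: PATID}
      - {name: DEATH_DATE, kind: date, required: true, nullable: true}
      - {name: DEATH_SOURCE, kind: coded, value_set: DEATH_SOURCE, required: false, nullable: true}
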