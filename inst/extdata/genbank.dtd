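<!ELEMENT genbank_db (genbank_entry*)>
<!ELEMENT genbank_entry (accession, locus, definition, origin)>
<!ATTLIST genbank_entry id CDATA #IMPLIED>
<!ELEMENT accession (#PCDATA)>
<!ELEMENT locus (#PCDATA)>
<!ELEMENT definition (#PCDATA)>
<!ELEMENT origin (#PCDATA)>
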