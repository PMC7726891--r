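<?xml version="1.0" encoding="UTF-8"?>
<!-- Schema for per-level playthrough logs. The original exergame's log
     layout is unpublished; this schema is a reconstruction of what is
     stored per level (player profile, level info, steps taken, and the
     full com(t) / if(t) series), and is the format this package reads
     and writes. -->
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema">
  <xs:element name="playthrough">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="player">
          <xs:complexType>
            <xs:attribute name="id" type="xs:string" use="required"/>
            <xs:attribute name="weight" type="xs:decimal" use="required"/>
            <xs:attribute name="age" type="xs:decimal"/>
            <xs:attribute name="sex" type="xs:string"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="level">
          <xs:complexType>
            <xs:attribute name="id" type="xs:string" use="required"/>
            <xs:attribute name="steps" type="xs:nonNegativeInteger"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="samples">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="s" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="t" type="xs:nonNegativeInteger"
                                use="required"/>
                  <xs:attribute name="x" type="xs:decimal" use="required"/>
                  <xs:attribute name="y" type="xs:decimal" use="required"/>
                  <xs:attribute name="if" type="xs:decimal" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="n" type="xs:nonNegativeInteger"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="steps" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="step" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="t" type="xs:nonNegativeInteger"
                                use="required"/>
                  <xs:attribute name="dir" use="required">
                    <xs:simpleType>
                      <xs:restriction base="xs:string">
                        <xs:enumeration value="Up"/>
                        <xs:enumeration value="Down"/>
                        <xs:enumeration value="Left"/>
                        <xs:enumeration value="Right"/>
                      </xs:restriction>
                    </xs:simpleType>
                  </xs:attribute>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="n" type="xs:nonNegativeInteger"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="raw" minOccurs="0">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="f" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="t" type="xs:nonNegativeInteger"
                                use="required"/>
                  <xs:attribute name="v" type="xs:string" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="n" type="xs:nonNegativeInteger"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
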